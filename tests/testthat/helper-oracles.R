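# Shared fixtures and independent oracles for the test suite.

# Independent thin-shell oracle for the shelled-sphere permittivity:
# eps_cell* ~ r * C*mem * eps_cyt* / (r * C*mem + eps_cyt*),
# with C*mem = c_eff - j * g_eff / omega. Used only as a cross-check of
# the full formula; never called by package code.
thin_shell_eps <- function(params, frequency) {
  omega <- 2 * pi * frequency
  cmem <- complex(real = params$c_eff, imaginary = -params$g_eff / omega)
  eps_cyt <- complex(real = EPS0 * params$eps_cyt_rel,
                     imaginary = -params$sigma_cyt / omega)
  r <- params$radius
  r * cmem * eps_cyt / (r * cmem + eps_cyt)
}

# Group-mean parameter rows (radius um, G_eff S/m^2, C_eff mF/m^2,
# sigma_cyt S/m) for the five measured chondrocyte groups.
table_rows <- list(
  equine_control = c(6.40, 8571, 14.5, 0.26),
  equine_chronic = c(6.58, 7857, 13.9, 0.29),
  equine_acute   = c(6.47, 6191, 10.3, 0.27),
  canine_control = c(6.3,  1139, 7.51, 0.22),
  canine_oa      = c(8.5,  782,  6.92, 0.24)
)

row_params <- function(row) as_si_params(row[1], row[2], row[3], row[4])

# Hand implementation of the pooled two-sample t statistic.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Random physically valid single-shell parameter set + medium.
random_physical_case <- function() {
  list(
    params = shell_params(
      radius = runif(1, 2e-6, 15e-6),
      g_eff = 10^runif(1, 0, 5),
      c_eff = 10^runif(1, -3, -1),
      sigma_cyt = runif(1, 0.05, 2),
      eps_cyt_rel = runif(1, 40, 80)
    ),
    medium = dep_medium(conductivity = runif(1, 1e-3, 2),
                        rel_permittivity = runif(1, 40, 80)),
    frequency = 10^runif(1, 1, 9)
  )
}
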