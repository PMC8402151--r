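# Dielectric core: complex permittivities, Clausius-Mossotti factor,
# shelled-sphere equivalent permittivity, DEP force prefactor, crossover
# location. Pure functions, vectorised over frequency.

#' Complex permittivity of a lossy dielectric
#'
#' The complex (absolute) permittivity `eps* = eps0*eps_rel - j*sigma/omega`
#' with `omega = 2*pi*f`. The imaginary part is non-positive for any
#' physical (non-negative) conductivity.
#'
#' @param rel_permittivity relative permittivity, dimensionless >= 1.
#' @param conductivity conductivity, S/m, >= 0.
#' @param frequency field frequency, Hz, > 0; may be a vector.
#' @return Complex vector, F/m, same length as `frequency`.
#' @export
#' @examples
#' complex_permittivity(78, 0.15, 1e6)
complex_permittivity <- function(rel_permittivity, conductivity, frequency) {
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("frequency must be positive", call. = FALSE)
  }
  if (any(conductivity < 0)) stop("conductivity must be >= 0", call. = FALSE)
  if (any(rel_permittivity < 1)) {
    stop("rel_permittivity must be >= 1", call. = FALSE)
  }
  complex(real = EPS0 * rel_permittivity,
          imaginary = -conductivity / (2 * pi * frequency))
}

#' Clausius-Mossotti factor
#'
#' The complex polarisability contrast
#' `K = (eps_p* - eps_m*) / (eps_p* + 2*eps_m*)` between particle and
#' suspending medium. For physical inputs (positive real parts,
#' non-positive imaginary parts) the real part lies in \[-0.5, 1\] and
#' the denominator cannot vanish.
#'
#' @param eps_particle complex permittivity of the particle, F/m.
#' @param eps_medium complex permittivity of the medium, F/m.
#' @return Complex vector, dimensionless.
#' @export
cm_factor <- function(eps_particle, eps_medium) {
  if (any(Re(eps_particle) <= 0) || any(Re(eps_medium) <= 0)) {
    stop("complex permittivities must have positive real part", call. = FALSE)
  }
  (eps_particle - eps_medium) / (eps_particle + 2 * eps_medium)
}

# Absolute membrane permittivity and conductivity implied by the
# specific (per-area) membrane parameters and the nominal thickness.
membrane_dielectrics <- function(params) {
  d <- params$membrane_thickness
  list(eps = params$c_eff * d,      # F/m
       sigma = params$g_eff * d)    # S/m
}

#' Equivalent complex permittivity of a single-shell cell
#'
#' Reduces the membrane-bounded sphere to one homogeneous equivalent
#' complex permittivity using the smeared shelled-sphere formula: with
#' `gamma = r / (r - d)` and `E = (eps_cyt* - eps_mem*) /
#' (eps_cyt* + 2*eps_mem*)`,
#' `eps_cell* = eps_mem* * (gamma^3 + 2*E) / (gamma^3 - E)`.
#' The membrane complex permittivity is built from the specific
#' quantities: conductivity `g_eff * d`, permittivity `c_eff * d`.
#' The result is suitable as the particle permittivity in [cm_factor()].
#'
#' @param params a [shell_params()] object.
#' @param frequency field frequency, Hz, > 0; may be a vector.
#' @return Complex vector, F/m.
#' @export
single_shell_permittivity <- function(params, frequency) {
  stopifnot(inherits(params, "shell_params"))
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("frequency must be positive", call. = FALSE)
  }
  r <- params$radius
  d <- params$membrane_thickness
  if (d >= r) stop("membrane thickness must be smaller than radius", call. = FALSE)

  omega <- 2 * pi * frequency
  mem <- membrane_dielectrics(params)
  eps_mem <- complex(real = mem$eps, imaginary = -mem$sigma / omega)
  eps_cyt <- complex(real = EPS0 * params$eps_cyt_rel,
                     imaginary = -params$sigma_cyt / omega)

  gamma3 <- (r / (r - d))^3
  e <- (eps_cyt - eps_mem) / (eps_cyt + 2 * eps_mem)
  eps_mem * (gamma3 + 2 * e) / (gamma3 - e)
}

#' Real part of the Clausius-Mossotti spectrum of a shelled cell
#'
#' Composes [single_shell_permittivity()] and [cm_factor()] across a
#' frequency grid: the frequency-dependent quantity a DEP well-plate
#' spectrum reports, bounded in \[-0.5, 1\].
#'
#' @param params a [shell_params()] object.
#' @param medium a [dep_medium()] object.
#' @param frequencies frequency grid, Hz, all > 0.
#' @return Numeric vector `Re[K(omega_i)]`, same length as `frequencies`.
#' @export
#' @examples
#' p <- as_si_params(6.40, 8571, 14.5, 0.26)
#' re_cm_spectrum(p, dep_medium(), c(1e3, 1e5, 1e7))
re_cm_spectrum <- function(params, medium, frequencies) {
  stopifnot(inherits(medium, "dep_medium"))
  eps_p <- single_shell_permittivity(params, frequencies)
  eps_m <- complex_permittivity(medium$rel_permittivity,
                                medium$conductivity, frequencies)
  Re(cm_factor(eps_p, eps_m))
}

#' Time-averaged DEP force on a spherical particle
#'
#' `F = 2*pi*eps_m*r^3*Re[K]*grad(E^2)`. The sign follows the sign of
#' `Re[K]`: positive DEP pulls the particle toward high-field regions.
#'
#' @param radius particle radius, m, > 0.
#' @param medium a [dep_medium()] object (supplies `eps_m`).
#' @param re_k real part of the Clausius-Mossotti factor.
#' @param grad_E_squared gradient of the squared field magnitude, V^2/m^3.
#' @return Force in newtons.
#' @export
dep_force_prefactor <- function(radius, medium, re_k, grad_E_squared) {
  stopifnot(inherits(medium, "dep_medium"))
  if (any(radius <= 0)) stop("radius must be > 0", call. = FALSE)
  2 * pi * EPS0 * medium$rel_permittivity * radius^3 * re_k * grad_E_squared
}

#' DEP crossover frequencies
#'
#' Locates every frequency in `(f_min, f_max)` at which `Re[K]` changes
#' sign, i.e. where the DEP force reverses direction. Sign changes are
#' bracketed on a log-spaced scan grid and refined by bisection
#' ([stats::uniroot()]) to relative tolerance 1e-9.
#'
#' @param params a [shell_params()] object.
#' @param medium a [dep_medium()] object.
#' @param f_min,f_max search band, Hz, `0 < f_min < f_max`.
#' @param n_scan number of scan points (>= 200 recommended).
#' @return Ascending numeric vector of crossover frequencies, possibly
#'   empty when `Re[K]` keeps one sign across the whole band.
#' @export
#' @examples
#' p <- as_si_params(6.40, 8571, 14.5, 0.26)
#' crossover_frequencies(p, dep_medium(), 1e3, 4.5e7)
crossover_frequencies <- function(params, medium, f_min, f_max,
                                  n_scan = 200L) {
  if (!is.finite(f_min) || !is.finite(f_max) || f_min <= 0 || f_min >= f_max) {
    stop("require 0 < f_min < f_max", call. = FALSE)
  }
  grid <- exp(seq(log(f_min), log(f_max), length.out = max(n_scan, 3L)))
  rek <- re_cm_spectrum(params, medium, grid)
  s <- sign(rek)
  roots <- numeric(0)
  for (i in which(s[-1] * s[-length(s)] < 0)) {
    root <- stats::uniroot(
      function(f) re_cm_spectrum(params, medium, f),
      lower = grid[i], upper = grid[i + 1],
      tol = 1e-9 * grid[i]
    )$root
    roots <- c(roots, root)
  }
  # exact zeros on the scan grid count as crossings too
  roots <- sort(unique(c(roots, grid[s == 0 & grid > f_min & grid < f_max])))
  roots
}
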