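# Internal helpers: RNG hygiene, truncated-normal draws, unit conversion.

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Normal draws truncated below at zero, by rejection. Errors out when the
# acceptance probability is below 1% (a pathological mean/sd combination).
rnorm_trunc_pos <- function(n, mean, sd, max_tries = 1000L) {
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (sd == 0) {
    if (any(mean <= 0)) stop("degenerate draw: non-positive constant", call. = FALSE)
    return(rep_len(mean, n))
  }
  if (stats::pnorm(0, mean, sd, lower.tail = FALSE) < 0.01) {
    stop("degenerate cohort spec: truncation would reject > 99% of draws",
         call. = FALSE)
  }
  out <- numeric(n)
  todo <- seq_len(n)
  for (i in seq_len(max_tries)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] <= 0]
    if (length(todo) == 0L) return(out)
  }
  stop("truncated-normal sampling failed to converge", call. = FALSE)
}

# Derive a per-sample RNG seed from a master seed and a sample index,
# kept inside the 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 8191) %% 2147483647)
}

#' Convert paper-unit dielectric parameters to an SI parameter set
#'
#' Group tables in this field report cell radius in micrometres, effective
#' membrane conductance in S/m^2, effective membrane capacitance in mF/m^2
#' and cytoplasmic conductivity in S/m. This helper builds a
#' [shell_params()] object (SI units: m, S/m^2, F/m^2, S/m) from those
#' conventions; [as_paper_units()] is its exact inverse.
#'
#' @param radius_um cell radius, micrometres.
#' @param g_eff effective (specific) membrane conductance, S/m^2.
#' @param c_eff_mF effective (specific) membrane capacitance, mF/m^2.
#' @param sigma_cyt cytoplasmic conductivity, S/m.
#' @param ... further arguments passed to [shell_params()]
#'   (`membrane_thickness`, `eps_cyt_rel`).
#' @return A `shell_params` object.
#' @seealso [as_paper_units()]
#' @export
#' @examples
#' p <- as_si_params(6.40, 8571, 14.5, 0.26)
#' as_paper_units(p)
as_si_params <- function(radius_um, g_eff, c_eff_mF, sigma_cyt, ...) {
  shell_params(radius = radius_um * 1e-6, g_eff = g_eff,
               c_eff = c_eff_mF * 1e-3, sigma_cyt = sigma_cyt, ...)
}

#' Report an SI parameter set in paper units
#'
#' @param params a [shell_params()] object.
#' @return Named numeric vector with components `radius_um`, `g_eff`
#'   (S/m^2), `c_eff_mF` (mF/m^2) and `sigma_cyt` (S/m).
#' @export
as_paper_units <- function(params) {
  stopifnot(inherits(params, "shell_params"))
  c(radius_um = params$radius * 1e6,
    g_eff = params$g_eff,
    c_eff_mF = params$c_eff * 1e3,
    sigma_cyt = params$sigma_cyt)
}
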