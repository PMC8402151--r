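#' Single-shell cell model parameters
#'
#' Parameter set for the single-shell (shelled-sphere) dielectric cell
#' model: a conducting cytoplasmic sphere wrapped in a thin, poorly
#' conducting membrane. The membrane is parameterised by its specific
#' (per-area) quantities — effective membrane conductance `g_eff` and
#' effective membrane capacitance `c_eff` — so the nominal membrane
#' thickness `d` only mediates the conversion to membrane conductivity
#' (`sigma_mem = g_eff * d`) and membrane permittivity
#' (`eps_mem = c_eff * d`); results are insensitive to `d` in the
#' thin-shell regime. All units SI.
#'
#' @param radius cell radius, m; > 0.
#' @param g_eff effective (specific) membrane conductance, S/m^2; >= 0.
#' @param c_eff effective (specific) membrane capacitance, F/m^2; > 0.
#' @param sigma_cyt cytoplasmic conductivity, S/m; > 0.
#' @param membrane_thickness membrane thickness d, m; default 5 nm, the
#'   conventional lipid-bilayer value. Must stay below `radius / 100`
#'   (thin-shell regime).
#' @param eps_cyt_rel cytoplasm relative permittivity (dimensionless,
#'   >= 1); default 60, the usual value for mammalian cytoplasm, held
#'   fixed rather than fitted.
#' @return An object of class `shell_params`.
#' @seealso [as_si_params()] for the paper-unit constructor.
#' @export
#' @examples
#' # healthy equine chondrocyte, group-mean values
#' shell_params(radius = 6.40e-6, g_eff = 8571, c_eff = 14.5e-3,
#'              sigma_cyt = 0.26)
shell_params <- function(radius, g_eff, c_eff, sigma_cyt,
                         membrane_thickness = 5e-9, eps_cyt_rel = 60) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
    x
  }
  radius <- num1(radius, "radius")
  g_eff <- num1(g_eff, "g_eff")
  c_eff <- num1(c_eff, "c_eff")
  sigma_cyt <- num1(sigma_cyt, "sigma_cyt")
  membrane_thickness <- num1(membrane_thickness, "membrane_thickness")
  eps_cyt_rel <- num1(eps_cyt_rel, "eps_cyt_rel")

  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (g_eff < 0) stop("g_eff must be >= 0", call. = FALSE)
  if (c_eff <= 0) stop("c_eff must be > 0", call. = FALSE)
  if (sigma_cyt <= 0) stop("sigma_cyt must be > 0", call. = FALSE)
  if (membrane_thickness <= 0) stop("membrane_thickness must be > 0", call. = FALSE)
  if (eps_cyt_rel < 1) stop("eps_cyt_rel must be >= 1", call. = FALSE)
  if (membrane_thickness >= radius / 100) {
    stop("membrane_thickness must be < radius / 100 (thin-shell regime)",
         call. = FALSE)
  }

  structure(list(radius = radius, g_eff = g_eff, c_eff = c_eff,
                 sigma_cyt = sigma_cyt,
                 membrane_thickness = membrane_thickness,
                 eps_cyt_rel = eps_cyt_rel),
            class = "shell_params")
}

#' @export
print.shell_params <- function(x, ...) {
  cat("Single-shell cell model parameters\n")
  cat(sprintf("  radius:              %.3g um\n", x$radius * 1e6))
  cat(sprintf("  G_eff:               %.4g S/m^2\n", x$g_eff))
  cat(sprintf("  C_eff:               %.4g mF/m^2\n", x$c_eff * 1e3))
  cat(sprintf("  sigma_cyt:           %.3g S/m\n", x$sigma_cyt))
  cat(sprintf("  membrane thickness:  %.3g nm\n", x$membrane_thickness * 1e9))
  cat(sprintf("  eps_cyt (relative):  %.3g\n", x$eps_cyt_rel))
  invisible(x)
}
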