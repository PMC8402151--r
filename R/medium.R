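#' Suspending-medium dielectric description
#'
#' Constructs the dielectric description of the DEP suspending medium.
#' The defaults reproduce the standard low-conductivity iso-osmotic
#' sucrose/dextrose medium used for mammalian-cell DEP: conductivity
#' adjusted to 0.15 S/m (150 mS/m) with PBS, relative permittivity 78
#' (essentially water at room temperature).
#'
#' @param conductivity medium conductivity, S/m; must be > 0.
#' @param rel_permittivity relative permittivity (dimensionless); must
#'   be >= 1.
#' @return An object of class `dep_medium`: a list with elements
#'   `conductivity` and `rel_permittivity`.
#' @export
#' @examples
#' dep_medium()                   # 0.15 S/m DEP buffer
#' dep_medium(conductivity = 0.01)
dep_medium <- function(conductivity = 0.15, rel_permittivity = 78) {
  if (!is.numeric(conductivity) || length(conductivity) != 1L ||
      !is.finite(conductivity) || conductivity <= 0) {
    stop("medium conductivity must be a single positive number (S/m)",
         call. = FALSE)
  }
  if (!is.numeric(rel_permittivity) || length(rel_permittivity) != 1L ||
      !is.finite(rel_permittivity) || rel_permittivity < 1) {
    stop("medium relative permittivity must be a single number >= 1",
         call. = FALSE)
  }
  structure(list(conductivity = conductivity,
                 rel_permittivity = rel_permittivity),
            class = "dep_medium")
}

#' @export
print.dep_medium <- function(x, ...) {
  cat("DEP suspending medium\n")
  cat(sprintf("  conductivity:         %g S/m\n", x$conductivity))
  cat(sprintf("  relative permittivity: %g\n", x$rel_permittivity))
  invisible(x)
}
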