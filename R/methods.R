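# S3 methods for dep_fit objects.

#' @export
print.dep_fit <- function(x, digits = 4, ...) {
  cat("Single-shell DEP spectrum fit\n")
  if (nzchar(x$spectrum$label)) cat("  spectrum:", x$spectrum$label, "\n")
  cat(sprintf("  status: %s | accepted: %s | Pearson R: %s\n",
              x$status, x$accepted,
              if (is.na(x$pearson_r)) "NA" else format(x$pearson_r, digits = digits)))
  if (!any(is.na(x$coefficients[1:3]))) {
    cat(sprintf("  G_eff:     %s S/m^2\n",
                format(x$coefficients[["g_eff"]], digits = digits)))
    cat(sprintf("  C_eff:     %s mF/m^2\n",
                format(x$coefficients[["c_eff"]] * 1e3, digits = digits)))
    cat(sprintf("  sigma_cyt: %s S/m\n",
                format(x$coefficients[["sigma_cyt"]], digits = digits)))
  }
  invisible(x)
}

#' Extract fitted single-shell parameters
#'
#' @param object a [dep_fit()] object.
#' @param ... unused.
#' @return Named numeric vector: `g_eff` (S/m^2), `c_eff` (F/m^2),
#'   `sigma_cyt` (S/m), `scale`, `offset` (a.u.).
#' @export
coef.dep_fit <- function(object, ...) object$coefficients

#' @export
fitted.dep_fit <- function(object, ...) object$fitted.values

#' @export
residuals.dep_fit <- function(object, ...) object$residuals

#' Summary of a DEP spectrum fit
#'
#' Reports the fitted parameters in the units customarily used for cell
#' dielectric tables (S/m^2, mF/m^2, S/m) along with the whole-cell
#' capacitance implied by the fixed radius, and the fit diagnostics.
#'
#' @param object a [dep_fit()] object.
#' @param ... unused.
#' @return An object of class `summary.dep_fit`.
#' @export
summary.dep_fit <- function(object, ...) {
  co <- object$coefficients
  s <- list(
    label = object$spectrum$label,
    g_eff = co[["g_eff"]],
    c_eff_mF = co[["c_eff"]] * 1e3,
    sigma_cyt = co[["sigma_cyt"]],
    scale = co[["scale"]], offset = co[["offset"]],
    radius_um = object$radius * 1e6,
    c_whole_pF = if (is.na(co[["c_eff"]])) NA_real_ else
      whole_cell_capacitance(co[["c_eff"]], object$radius) * 1e12,
    pearson_r = object$pearson_r,
    accepted = object$accepted,
    status = object$status,
    residual_norm = object$residual_norm,
    n_points = length(object$spectrum$frequencies)
  )
  class(s) <- "summary.dep_fit"
  s
}

#' @export
print.summary.dep_fit <- function(x, digits = 4, ...) {
  cat("Single-shell DEP spectrum fit\n")
  if (nzchar(x$label)) cat("  spectrum:   ", x$label, "\n")
  cat(sprintf("  points:      %d\n", x$n_points))
  cat(sprintf("  radius:      %.3g um (fixed)\n", x$radius_um))
  cat("  Extracted parameters:\n")
  cat(sprintf("    G_eff      %s S/m^2\n", format(x$g_eff, digits = digits)))
  cat(sprintf("    C_eff      %s mF/m^2\n", format(x$c_eff_mF, digits = digits)))
  cat(sprintf("    sigma_cyt  %s S/m\n", format(x$sigma_cyt, digits = digits)))
  cat(sprintf("    C_whole    %s pF\n", format(x$c_whole_pF, digits = digits)))
  cat(sprintf("  scale %s, offset %s (a.u.)\n",
              format(x$scale, digits = digits), format(x$offset, digits = digits)))
  cat(sprintf("  Pearson R %s; residual norm %s; %s (%s)\n",
              format(x$pearson_r, digits = digits),
              format(x$residual_norm, digits = digits),
              if (isTRUE(x$accepted)) "ACCEPTED" else "EXCLUDED", x$status))
  invisible(x)
}

#' Predict model intensities at new frequencies
#'
#' Evaluates `scale * Re[K(omega)] + offset` at the requested
#' frequencies using the fitted parameters.
#'
#' @param object a [dep_fit()] object.
#' @param newdata optional numeric vector of frequencies (Hz) or a data
#'   frame with a `frequency_hz` column; defaults to the fitted grid.
#' @param ... unused.
#' @return Numeric vector of model intensities, a.u.
#' @export
predict.dep_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  f <- if (is.data.frame(newdata)) newdata$frequency_hz else as.numeric(newdata)
  co <- object$coefficients
  p <- shell_params_unchecked(object$radius, co[["g_eff"]], co[["c_eff"]],
                              co[["sigma_cyt"]],
                              object$control$membrane_thickness,
                              object$control$eps_cyt_rel)
  as.numeric(co[["scale"]] * re_cm_spectrum(p, object$medium, f) + co[["offset"]])
}

#' Simulate spectra from a fitted model
#'
#' Draws `nsim` new spectra from the fitted single-shell model with
#' Gaussian well noise at the residual standard deviation (or a
#' supplied `noise_sd`).
#'
#' @param object a [dep_fit()] object.
#' @param nsim number of spectra.
#' @param seed integer seed (optional).
#' @param noise_sd noise standard deviation; default the residual SD.
#' @param ... unused.
#' @return A list of [dep_spectrum()] objects of length `nsim`.
#' @export
simulate.dep_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- stats::sd(object$residuals)
  mu <- object$fitted.values
  f <- object$spectrum$frequencies
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    dep_spectrum(f, mu + stats::rnorm(length(mu), 0, noise_sd),
                 label = sprintf("%s_sim%d", object$spectrum$label, i))
  }))
}

#' Plot a DEP spectrum fit
#'
#' Observed intensities against frequency (log axis) with the fitted
#' single-shell curve evaluated on a fine grid.
#'
#' @param x a [dep_fit()] object.
#' @param n_curve points in the fitted curve (default 200).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dep_fit <- function(x, n_curve = 200L, ...) {
  f <- x$spectrum$frequencies
  graphics::plot(f, x$spectrum$intensities, log = "x",
                 xlab = "Frequency (Hz)", ylab = "Intensity change (a.u.)",
                 main = sprintf("Single-shell fit (R = %.3f%s)",
                                x$pearson_r,
                                if (x$accepted) "" else ", excluded"), ...)
  fg <- exp(seq(log(min(f)), log(max(f)), length.out = n_curve))
  graphics::lines(fg, predict(x, fg), col = "firebrick", lwd = 2)
  invisible(x)
}
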