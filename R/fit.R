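# Spectrum fitting: bounded multi-start Levenberg-Marquardt least squares
# of the single-shell Re[K] model against well-plate intensities.

#' Pearson product-moment correlation with validation
#'
#' Correlation between model values and observations, used as the fit
#' acceptance statistic. Errors out for inputs shorter than 3 or with
#' zero variance, where the correlation is undefined.
#'
#' @param model_values,observed numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(model_values, observed) {
  if (length(model_values) != length(observed)) {
    stop("model_values and observed must have equal length", call. = FALSE)
  }
  if (length(observed) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(model_values) == 0 || stats::sd(observed) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(model_values, observed)
}

#' Control parameters for [dep_fit()]
#'
#' Bounds bracket literature values for mammalian cells with wide
#' margins; the fixed dielectric constants (`membrane_thickness`,
#' `eps_cyt_rel`) mirror the [shell_params()] defaults and are exposed
#' here so alternative conventions can be used without touching the
#' model code.
#'
#' By default the additive intensity baseline is not a free parameter
#' (`fit_offset = FALSE`): well-plate DEP readers report the *relative*
#' band-intensity change, which is zero-baselined by construction, and
#' at realistic noise a free offset makes the inversion ill-posed — a
#' nearly flat high-conductance spectrum stretched by a large gain can
#' shadow the true solution. Set `fit_offset = TRUE` to fit a baseline
#' when the instrument export carries one (noise-free or low-noise
#' spectra remain exactly identifiable with it).
#'
#' @param g_eff_bounds bounds for membrane conductance, S/m^2.
#' @param c_eff_bounds bounds for membrane capacitance, F/m^2.
#' @param sigma_cyt_bounds bounds for cytoplasmic conductivity, S/m.
#' @param fit_offset logical; fit the additive baseline (default FALSE).
#' @param n_starts starting points per parameter axis of the log-spaced
#'   multi-start grid (default 3, i.e. 27 starts).
#' @param accept_threshold Pearson-R acceptance threshold; fits with
#'   `R <= accept_threshold` are excluded (default 0.9, strict
#'   inequality).
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @param membrane_thickness nominal membrane thickness, m.
#' @param eps_cyt_rel fixed cytoplasm relative permittivity.
#' @return A list of class `dep_fit_control`.
#' @export
dep_fit_control <- function(g_eff_bounds = c(0, 1e5),
                            c_eff_bounds = c(1e-3, 1e-1),
                            sigma_cyt_bounds = c(0.01, 2),
                            fit_offset = FALSE,
                            n_starts = 3L,
                            accept_threshold = 0.9,
                            maxiter = 200L,
                            membrane_thickness = 5e-9,
                            eps_cyt_rel = 60) {
  chk <- function(b, nm) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop(sprintf("%s must be c(lower, upper) with lower < upper", nm),
           call. = FALSE)
    }
  }
  chk(g_eff_bounds, "g_eff_bounds")
  chk(c_eff_bounds, "c_eff_bounds")
  chk(sigma_cyt_bounds, "sigma_cyt_bounds")
  structure(list(g_eff_bounds = g_eff_bounds, c_eff_bounds = c_eff_bounds,
                 sigma_cyt_bounds = sigma_cyt_bounds,
                 fit_offset = isTRUE(fit_offset),
                 n_starts = max(1L, as.integer(n_starts)),
                 accept_threshold = accept_threshold,
                 maxiter = as.integer(maxiter),
                 membrane_thickness = membrane_thickness,
                 eps_cyt_rel = eps_cyt_rel),
            class = "dep_fit_control")
}

# log-spaced interior grid of starting values within [lo, hi]
start_grid <- function(lo, hi, n) {
  lo <- max(lo, hi * 1e-4)   # keep log-spacing finite when lo == 0
  exp(seq(log(lo), log(hi), length.out = n + 2L))[seq_len(n) + 1L]
}

# fast unvalidated parameter bundle for use inside the optimiser loop
shell_params_unchecked <- function(radius, g_eff, c_eff, sigma_cyt, d, eps_cyt_rel) {
  structure(list(radius = radius, g_eff = g_eff, c_eff = c_eff,
                 sigma_cyt = sigma_cyt, membrane_thickness = d,
                 eps_cyt_rel = eps_cyt_rel),
            class = "shell_params")
}

#' Fit the single-shell model to a DEP spectrum
#'
#' Extracts effective membrane conductance (`g_eff`, S/m^2), effective
#' membrane capacitance (`c_eff`, F/m^2) and cytoplasmic conductivity
#' (`sigma_cyt`, S/m) from one light-intensity spectrum by minimising
#' the sum of squared residuals between
#' `scale * Re[K(omega_i; g_eff, c_eff, sigma_cyt)] + offset` and the
#' observed intensities. The cell radius is fixed (measured per
#' sample); the intensity gain `scale` is a free nuisance parameter for
#' the instrument's intensity mapping, and an additive baseline
#' `offset` can be freed via [dep_fit_control()]. The optimiser is bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm]) restarted
#' from a log-spaced grid of initial values; the lowest residual wins,
#' ties broken by lower `g_eff`. A fit is `accepted` only when the
#' optimiser converged and the Pearson correlation between best-fit
#' model and data exceeds the acceptance threshold (default R > 0.9;
#' fits at or below it are excluded).
#'
#' @param spectrum a [dep_spectrum()] (or anything coercible via
#'   `dep_spectrum(frequencies, intensities)`), at least 6 points.
#' @param medium a [dep_medium()] object.
#' @param radius cell radius, m, > 0.
#' @param control a [dep_fit_control()] list.
#' @return An object of class `dep_fit` with components `coefficients`
#'   (named: g_eff, c_eff, sigma_cyt, scale, offset), `pearson_r`,
#'   `accepted`, `converged`, `status`, `residual_norm` (sqrt of the
#'   summed squared residuals), `n_restarts_used`, `fitted.values`,
#'   `residuals`, plus the inputs needed by the methods. Constant
#'   (degenerate) intensity data yields a rejected fit with
#'   `status = "degenerate-data"` and `pearson_r = NA`.
#' @seealso [coef.dep_fit()], [predict.dep_fit()], [plot.dep_fit()],
#'   [simulate.dep_fit()], [whole_cell_capacitance()]
#' @export
#' @examples
#' p <- as_si_params(6.40, 8571, 14.5, 0.26)
#' s <- simulate_spectrum(p, dep_medium(), noise_sd = 0.02, seed = 7)
#' fit <- dep_fit(s, dep_medium(), radius = 6.40e-6)
#' coef(fit)
dep_fit <- function(spectrum, medium, radius, control = dep_fit_control()) {
  stopifnot(inherits(medium, "dep_medium"), inherits(control, "dep_fit_control"))
  if (!inherits(spectrum, "dep_spectrum")) {
    stop("spectrum must be a dep_spectrum object", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a single positive number (m)", call. = FALSE)
  }
  f <- spectrum$frequencies
  y <- spectrum$intensities
  if (length(f) < 6L) {
    stop("insufficient data: need at least 6 spectrum points", call. = FALSE)
  }

  d <- control$membrane_thickness
  eps_cyt_rel <- control$eps_cyt_rel
  fit_offset <- control$fit_offset

  out <- structure(list(coefficients = c(g_eff = NA_real_, c_eff = NA_real_,
                                         sigma_cyt = NA_real_, scale = NA_real_,
                                         offset = NA_real_),
                        pearson_r = NA_real_, accepted = FALSE,
                        converged = FALSE, status = "not-fitted",
                        residual_norm = NA_real_, n_restarts_used = 0L,
                        fitted.values = rep(NA_real_, length(y)),
                        residuals = rep(NA_real_, length(y)),
                        spectrum = spectrum, medium = medium, radius = radius,
                        control = control),
                   class = "dep_fit")

  if (stats::sd(y) == 0) {
    out$status <- "degenerate-data"
    return(out)
  }

  model_curve <- function(g, c_, s) {
    p <- shell_params_unchecked(radius, g, c_, s, d, eps_cyt_rel)
    re_cm_spectrum(p, medium, f)
  }
  resid_fun <- function(theta) {
    k <- model_curve(theta[1], theta[2], theta[3])
    mu <- theta[4] * k + if (fit_offset) theta[5] else 0
    mu - y
  }

  lower <- c(control$g_eff_bounds[1], control$c_eff_bounds[1],
             control$sigma_cyt_bounds[1], .Machine$double.xmin)
  upper <- c(control$g_eff_bounds[2], control$c_eff_bounds[2],
             control$sigma_cyt_bounds[2], Inf)
  if (fit_offset) {
    lower <- c(lower, -Inf)
    upper <- c(upper, Inf)
  }

  n <- control$n_starts
  starts <- expand.grid(
    g = start_grid(control$g_eff_bounds[1], control$g_eff_bounds[2], n),
    c = start_grid(control$c_eff_bounds[1], control$c_eff_bounds[2], n),
    s = start_grid(control$sigma_cyt_bounds[1], control$sigma_cyt_bounds[2], n)
  )

  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    g0 <- starts$g[i]; c0 <- starts$c[i]; s0 <- starts$s[i]
    k0 <- model_curve(g0, c0, s0)
    # linear pre-fit of the nuisance parameters at this start
    if (stats::sd(k0) > 0) {
      if (fit_offset) {
        b <- stats::coef(stats::lm.fit(cbind(1, k0), y))
        scale0 <- b[2]; offset0 <- b[1]
      } else {
        scale0 <- sum(k0 * y) / sum(k0 * k0); offset0 <- 0
      }
    } else {
      scale0 <- 1; offset0 <- if (fit_offset) mean(y) else 0
    }
    if (!is.finite(scale0) || scale0 <= 0) {
      scale0 <- max(diff(range(y)), .Machine$double.eps)
      offset0 <- if (fit_offset) mean(y) else 0
    }
    theta0 <- unname(c(g0, c0, s0, scale0, if (fit_offset) offset0))

    res <- tryCatch(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = control$maxiter, ftol = 1e-12,
                           ptol = 1e-12, gtol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    n_used <- n_used + 1L
    dev <- res$deviance
    if (is.null(best) ||
        dev < best$deviance * (1 - 1e-12) ||
        (abs(dev - best$deviance) <= 1e-12 * max(dev, best$deviance) &&
         res$par[1] < best$par[1])) {
      best <- res
    }
  }

  out$n_restarts_used <- n_used
  if (is.null(best)) {
    out$status <- "optimizer-failed"
    return(out)
  }

  theta <- unname(best$par)
  coefs <- c(g_eff = theta[1], c_eff = theta[2], sigma_cyt = theta[3],
             scale = theta[4], offset = if (fit_offset) theta[5] else 0)
  mu <- coefs["scale"] * model_curve(coefs["g_eff"], coefs["c_eff"],
                                     coefs["sigma_cyt"]) + coefs["offset"]

  out$coefficients <- coefs
  out$fitted.values <- as.numeric(mu)
  out$residuals <- as.numeric(mu - y)
  out$residual_norm <- sqrt(sum(out$residuals^2))
  out$converged <- best$info %in% 1:4
  out$status <- if (out$converged) "converged" else "not-converged"

  r <- tryCatch(pearson_r(out$fitted.values, y), error = function(e) NA_real_)
  out$pearson_r <- r
  if (is.na(r)) out$status <- "degenerate-fit"
  out$accepted <- isTRUE(out$converged && !is.na(r) &&
                           r > control$accept_threshold)
  out
}

#' Whole-cell capacitance from specific membrane capacitance
#'
#' Multiplies the specific (per-area) membrane capacitance by the
#' spherical cell surface area: `C = c_eff * 4 * pi * radius^2`. This
#' is the quantity patch-clamp electrophysiology reports in picofarads.
#'
#' @param c_eff effective membrane capacitance, F/m^2, > 0.
#' @param radius cell radius, m, >= 0.
#' @return Capacitance in farads (multiply by 1e12 for pF).
#' @export
#' @examples
#' whole_cell_capacitance(14.5e-3, 6.40e-6) * 1e12  # ~7.5 pF
whole_cell_capacitance <- function(c_eff, radius) {
  if (any(c_eff <= 0)) stop("c_eff must be > 0", call. = FALSE)
  if (any(radius < 0)) stop("radius must be >= 0", call. = FALSE)
  c_eff * 4 * pi * radius^2
}

#' Write a machine-readable fit report
#'
#' Serialises a [dep_fit()] to JSON: all extracted parameters and fit
#' diagnostics plus the fixed-constant block used (membrane thickness,
#' medium permittivity and conductivity, cytoplasm permittivity,
#' radius) for full provenance.
#'
#' @param fit a `dep_fit` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "dep_fit"))
  co <- as.list(fit$coefficients)
  rep <- list(
    label = fit$spectrum$label,
    g_eff = co$g_eff, c_eff = co$c_eff, sigma_cyt = co$sigma_cyt,
    scale = co$scale, offset = co$offset,
    pearson_r = fit$pearson_r, accepted = fit$accepted,
    converged = fit$converged, status = fit$status,
    residual_norm = fit$residual_norm,
    n_restarts_used = fit$n_restarts_used,
    fixed_constants = list(
      membrane_thickness_m = fit$control$membrane_thickness,
      eps_medium_rel = fit$medium$rel_permittivity,
      sigma_medium_S_per_m = fit$medium$conductivity,
      eps_cyt_rel = fit$control$eps_cyt_rel,
      radius_m = fit$radius
    )
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
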