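# Synthetic cohort generation: groups of cells with radii and dielectric
# parameters drawn per biological repeat, expanded into noisy per-repeat
# spectra, with ground truth retained for recovery scoring.

#' Recipe for one synthetic experimental group
#'
#' Describes a cohort in the units group tables use: radius in
#' micrometres, membrane conductance in S/m^2, membrane capacitance in
#' mF/m^2, cytoplasmic conductivity in S/m. Group-level SDs are
#' interpreted as between-biological-repeat variability; technical
#' repeats of one biological repeat share the drawn cell parameters and
#' differ only through measurement noise.
#'
#' @param group_label group name.
#' @param radius_mean,radius_sd cell radius mean and SD, micrometres.
#' @param g_eff_mean,g_eff_sd membrane conductance mean and SD, S/m^2.
#' @param c_eff_mean,c_eff_sd membrane capacitance mean and SD, mF/m^2.
#' @param sigma_cyt_mean,sigma_cyt_sd cytoplasmic conductivity mean and
#'   SD, S/m.
#' @param n_biological biological repeats (default 4, >= 2).
#' @param n_technical technical repeats per biological repeat
#'   (default 3).
#' @param noise_sd well-noise SD, a.u.; `NA` (default) uses 5% of the
#'   noiseless spectrum's peak-to-peak amplitude, which leaves most
#'   fitted Pearson-R values above the 0.9 acceptance threshold.
#' @param seed master seed for the cohort (integer).
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec("control", 6.40, 0.12, 8571, 1010, 14.5, 0.01, 0.26, 0.01)
cohort_spec <- function(group_label,
                        radius_mean, radius_sd,
                        g_eff_mean, g_eff_sd,
                        c_eff_mean, c_eff_sd,
                        sigma_cyt_mean, sigma_cyt_sd,
                        n_biological = 4L, n_technical = 3L,
                        noise_sd = NA_real_, seed = 1L) {
  means <- c(radius_mean, g_eff_mean, c_eff_mean, sigma_cyt_mean)
  sds <- c(radius_sd, g_eff_sd, c_eff_sd, sigma_cyt_sd)
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("all cohort means must be positive", call. = FALSE)
  }
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all cohort SDs must be non-negative", call. = FALSE)
  }
  if (n_biological < 2L) stop("n_biological must be >= 2", call. = FALSE)
  if (n_technical < 1L) stop("n_technical must be >= 1", call. = FALSE)
  structure(list(group_label = as.character(group_label),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 g_eff_mean = g_eff_mean, g_eff_sd = g_eff_sd,
                 c_eff_mean = c_eff_mean, c_eff_sd = c_eff_sd,
                 sigma_cyt_mean = sigma_cyt_mean, sigma_cyt_sd = sigma_cyt_sd,
                 n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec '%s': %d biological x %d technical repeats\n",
              x$group_label, x$n_biological, x$n_technical))
  cat(sprintf("  radius     %g (+/- %g) um\n", x$radius_mean, x$radius_sd))
  cat(sprintf("  G_eff      %g (+/- %g) S/m^2\n", x$g_eff_mean, x$g_eff_sd))
  cat(sprintf("  C_eff      %g (+/- %g) mF/m^2\n", x$c_eff_mean, x$c_eff_sd))
  cat(sprintf("  sigma_cyt  %g (+/- %g) S/m\n", x$sigma_cyt_mean, x$sigma_cyt_sd))
  invisible(x)
}

#' Chondrocyte cohort presets
#'
#' The five group-mean (+/- SD) parameter sets measured for articular
#' chondrocytes by well-plate DEP: equine cells untreated (control),
#' chronically TEA-treated and acutely TEA-treated, and canine cells
#' untreated vs. cytokine-stimulated (in-vitro osteoarthritis model).
#' Each preset carries 4 biological x 3 technical repeats.
#'
#' @param seed master seed applied to every preset.
#' @return Named list of five [cohort_spec()] objects:
#'   `equine_control`, `equine_chronic`, `equine_acute`,
#'   `canine_control`, `canine_oa`.
#' @export
#' @examples
#' table_presets()$equine_acute
table_presets <- function(seed = 1L) {
  list(
    equine_control = cohort_spec("equine_control", 6.40, 0.12,
                                 8571, 1010, 14.5, 0.01, 0.26, 0.01,
                                 seed = seed),
    equine_chronic = cohort_spec("equine_chronic", 6.58, 0.18,
                                 7857, 1190, 13.9, 1.22, 0.29, 0.03,
                                 seed = seed),
    equine_acute = cohort_spec("equine_acute", 6.47, 0.07,
                               6191, 738, 10.3, 1.47, 0.27, 0.05,
                               seed = seed),
    canine_control = cohort_spec("canine_control", 6.3, 0.82,
                                 1139, 112, 7.51, 2.6, 0.22, 0.06,
                                 seed = seed),
    canine_oa = cohort_spec("canine_oa", 8.5, 0.97,
                            782, 183, 6.92, 3.5, 0.24, 0.06,
                            seed = seed)
  )
}

#' Generate a synthetic cohort of DEP spectra
#'
#' For each biological repeat, draws one (radius, g_eff, c_eff,
#' sigma_cyt) tuple from independent normal distributions truncated at
#' zero; for each technical repeat, simulates one noisy spectrum from
#' that tuple. The master seed fixes both the parameter draws and the
#' per-sample noise streams, so a cohort is fully reproducible.
#'
#' @param spec a [cohort_spec()].
#' @param medium a [dep_medium()] object.
#' @param frequencies frequency grid, Hz.
#' @param scale,offset intensity mapping used for every spectrum.
#' @return An object of class `dep_cohort`: a list of samples, each a
#'   list with `group_label`, `biological_id`, `technical_id`,
#'   `true_params` (a [shell_params()]), `radius_um` and `spectrum`.
#' @export
#' @examples
#' cohort <- generate_cohort(table_presets(seed = 42)$equine_control)
#' length(cohort)  # 4 x 3 samples
generate_cohort <- function(spec, medium = dep_medium(),
                            frequencies = default_frequencies(),
                            scale = 1, offset = 0) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(medium, "dep_medium"))
  samples <- with_seed(spec$seed, {
    draws <- list(
      radius = rnorm_trunc_pos(spec$n_biological, spec$radius_mean, spec$radius_sd),
      g_eff = rnorm_trunc_pos(spec$n_biological, spec$g_eff_mean, spec$g_eff_sd),
      c_eff = rnorm_trunc_pos(spec$n_biological, spec$c_eff_mean, spec$c_eff_sd),
      sigma_cyt = rnorm_trunc_pos(spec$n_biological, spec$sigma_cyt_mean,
                                  spec$sigma_cyt_sd)
    )
    out <- vector("list", spec$n_biological * spec$n_technical)
    idx <- 0L
    for (b in seq_len(spec$n_biological)) {
      params <- as_si_params(draws$radius[b], draws$g_eff[b],
                             draws$c_eff[b], draws$sigma_cyt[b])
      clean <- re_cm_spectrum(params, medium, frequencies) * scale + offset
      noise_sd <- if (is.na(spec$noise_sd)) {
        0.05 * diff(range(clean))
      } else {
        spec$noise_sd
      }
      for (t in seq_len(spec$n_technical)) {
        idx <- idx + 1L
        sim <- simulate_spectrum(
          params, medium, frequencies, scale = scale, offset = offset,
          noise_sd = noise_sd,
          seed = derive_seed(spec$seed, idx),
          label = sprintf("%s_b%d_t%d", spec$group_label, b, t)
        )
        out[[idx]] <- list(group_label = spec$group_label,
                           biological_id = b, technical_id = t,
                           true_params = params,
                           radius_um = draws$radius[b],
                           spectrum = sim)
      }
    }
    out
  })
  structure(samples, class = "dep_cohort", spec = spec)
}

#' @export
print.dep_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Synthetic DEP cohort '%s': %d samples (%d biological x %d technical)\n",
              spec$group_label, length(x), spec$n_biological, spec$n_technical))
  invisible(x)
}

#' Ground-truth manifest of one or more cohorts
#'
#' @param cohorts a `dep_cohort` or list of them.
#' @return Data frame with one row per sample: group, ids, radius (um)
#'   and the generating parameters in table units.
#' @export
cohort_manifest <- function(cohorts) {
  if (inherits(cohorts, "dep_cohort")) cohorts <- list(cohorts)
  rows <- lapply(cohorts, function(co) {
    do.call(rbind, lapply(co, function(s) {
      pu <- as_paper_units(s$true_params)
      data.frame(group = s$group_label, biological_id = s$biological_id,
                 technical_id = s$technical_id,
                 radius_um = pu[["radius_um"]], g_eff = pu[["g_eff"]],
                 c_eff_mF = pu[["c_eff_mF"]], sigma_cyt = pu[["sigma_cyt"]])
    }))
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk as spectrum CSVs plus a manifest
#'
#' Lays out one CSV per sample under `<dir>/<group>/<bio>/<tech>.csv`
#' and writes `manifest.csv` (ids, radius, true parameters) at the top
#' level for recovery scoring.
#'
#' @param cohorts a `dep_cohort` or list of them.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohorts, dir) {
  if (inherits(cohorts, "dep_cohort")) cohorts <- list(cohorts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (co in cohorts) {
    for (s in co) {
      sub <- file.path(dir, s$group_label, sprintf("bio%02d", s$biological_id))
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      write_dep_spectrum(s$spectrum,
                         file.path(sub, sprintf("tech%02d.csv", s$technical_id)))
    }
  }
  utils::write.csv(cohort_manifest(cohorts), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read or write a cohort spec as JSON
#'
#' Field names in the JSON match the [cohort_spec()] arguments.
#'
#' @param spec a [cohort_spec()] (for writing).
#' @param path JSON file path.
#' @return `read_cohort_spec()` returns a [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$noise_sd)) x$noise_sd <- NA_real_
  do.call(cohort_spec, x)
}
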