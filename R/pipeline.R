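# Study pipeline: per-spectrum fitting, Pearson-R exclusion, repeat
# aggregation, group summaries in table units, pairwise t-tests and
# parameter-recovery scoring against a ground-truth manifest.

#' Fit every spectrum of a synthetic cohort
#'
#' Runs [dep_fit()] on each sample with the radius fixed at the
#' sample's own (measured) radius and collects the results in a flat
#' table.
#'
#' @param cohort a `dep_cohort` from [generate_cohort()], or a list of
#'   sample lists with `group_label`, `biological_id`, `technical_id`,
#'   `radius_um` and `spectrum` entries (e.g. read back from disk).
#' @param medium a [dep_medium()] object.
#' @param control a [dep_fit_control()] list.
#' @return Data frame, one row per spectrum: ids, radius, fitted
#'   parameters in table units (`g_eff` S/m^2, `c_eff_mF` mF/m^2,
#'   `sigma_cyt` S/m), `pearson_r`, `accepted`, `converged`, `status`.
#' @export
fit_cohort <- function(cohort, medium = dep_medium(),
                       control = dep_fit_control()) {
  rows <- lapply(cohort, function(s) {
    fit <- dep_fit(s$spectrum, medium, s$radius_um * 1e-6, control)
    co <- coef(fit)
    data.frame(group = s$group_label,
               biological_id = s$biological_id,
               technical_id = s$technical_id,
               radius_um = s$radius_um,
               g_eff = co[["g_eff"]],
               c_eff_mF = co[["c_eff"]] * 1e3,
               sigma_cyt = co[["sigma_cyt"]],
               pearson_r = fit$pearson_r,
               accepted = fit$accepted,
               converged = fit$converged,
               status = fit$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate technical repeats into per-biological estimates
#'
#' Averages the accepted technical fits of each biological repeat
#' (arithmetic mean per parameter). Biological repeats whose technical
#' fits were all excluded are dropped with a warning; a group with no
#' accepted fits at all is an error. Whole-cell capacitance is derived
#' per biological repeat from its own radius and mean `c_eff`.
#'
#' @param fits the fit table from [fit_cohort()].
#' @return Data frame, one row per retained biological repeat: ids,
#'   radius, parameter means, `c_whole_pF`, and technical-level
#'   exclusion counts (`n_tech_accepted`, `n_tech_excluded`).
#' @export
aggregate_repeats <- function(fits) {
  if (nrow(fits) == 0L) stop("no fits to aggregate", call. = FALSE)
  for (g in unique(fits$group)) {
    if (!any(fits$accepted[fits$group == g])) {
      stop(sprintf("group '%s' has no accepted fits", g), call. = FALSE)
    }
  }
  key <- interaction(fits$group, fits$biological_id, drop = TRUE)
  rows <- lapply(split(fits, key), function(df) {
    acc <- df[df$accepted, , drop = FALSE]
    if (nrow(acc) == 0L) {
      warning(sprintf("dropping biological repeat %s/%d: all technical fits excluded",
                      df$group[1], df$biological_id[1]), call. = FALSE)
      return(NULL)
    }
    data.frame(group = df$group[1],
               biological_id = df$biological_id[1],
               radius_um = acc$radius_um[1],
               g_eff = mean(acc$g_eff),
               c_eff_mF = mean(acc$c_eff_mF),
               sigma_cyt = mean(acc$sigma_cyt),
               c_whole_pF = whole_cell_capacitance(
                 mean(acc$c_eff_mF) * 1e-3, acc$radius_um[1] * 1e-6) * 1e12,
               n_tech_accepted = nrow(acc),
               n_tech_excluded = nrow(df) - nrow(acc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$biological_id), , drop = FALSE]
}

#' Summarise per-biological estimates into a group table
#'
#' Means and SDs per group, in the units group tables customarily use
#' (um, S/m^2, mF/m^2, S/m, pF). Whole-cell capacitance is summarised
#' from the per-repeat values (each computed from its own radius and
#' `c_eff`), not from the product of group means. `n_accepted` and
#' `n_excluded` count biological repeats retained vs. dropped, so their
#' sum equals the number of fitted biological repeats.
#'
#' @param estimates the table from [aggregate_repeats()].
#' @param fits optional original fit table from [fit_cohort()], used to
#'   count dropped biological repeats and technical exclusions.
#' @return Data frame, one row per group, with `n_accepted`,
#'   `n_excluded`, technical-level counts and `<param>_mean` /
#'   `<param>_sd` columns.
#' @export
summarize_group <- function(estimates, fits = NULL) {
  rows <- lapply(split(estimates, estimates$group), function(df) {
    if (nrow(df) < 2L) {
      stop(sprintf("group '%s' has fewer than 2 biological estimates; SD undefined",
                   df$group[1]), call. = FALSE)
    }
    n_fitted_bio <- if (is.null(fits)) nrow(df) else {
      length(unique(fits$biological_id[fits$group == df$group[1]]))
    }
    out <- data.frame(group = df$group[1],
                      n_accepted = nrow(df),
                      n_excluded = n_fitted_bio - nrow(df),
                      n_tech_accepted = sum(df$n_tech_accepted),
                      n_tech_excluded = if (is.null(fits)) {
                        sum(df$n_tech_excluded)
                      } else {
                        sum(!fits$accepted[fits$group == df$group[1]])
                      },
                      stringsAsFactors = FALSE)
    for (p in c("radius_um", "g_eff", "c_eff_mF", "sigma_cyt", "c_whole_pF")) {
      out[[paste0(p, "_mean")]] <- mean(df[[p]])
      out[[paste0(p, "_sd")]] <- stats::sd(df[[p]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# significance stars at the conventional thresholds
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "****",
                ifelse(p < 1e-3, "***",
                       ifelse(p < 1e-2, "**",
                              ifelse(p < 0.05, "*", "ns")))))
}

#' Unpaired two-tailed t-test between two groups
#'
#' Student's pooled-variance t-test by default, Welch's as an option;
#' two-tailed p from the t distribution. Swapping the groups negates t
#' and leaves p unchanged. When both groups have zero variance the test
#' is degenerate: equal means give `status = "undefined"` with `NA`
#' statistics; unequal means give an infinite t with p = 0 and
#' `status = "zero-variance"`.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param parameter optional label for the compared quantity.
#' @param group_a,group_b optional group labels.
#' @return An object of class `dep_comparison`: list with
#'   `t_statistic`, `df`, `p_value`, `stars`, `variant`, `status` and
#'   the labels.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0214
compare_groups <- function(a, b, variant = c("pooled", "welch"),
                           parameter = "", group_a = "A", group_b = "B") {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  out <- list(group_a = group_a, group_b = group_b, parameter = parameter,
              t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
              stars = NA_character_, variant = variant, status = "ok")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      out$status <- "undefined"   # zero variance, equal means: t is 0/0
    } else {
      out$t_statistic <- sign(mean(a) - mean(b)) * Inf
      out$p_value <- 0
      out$stars <- "****"
      out$status <- "zero-variance"
    }
    class(out) <- "dep_comparison"
    return(out)
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  out$t_statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out$stars <- p_stars(tt$p.value)
  class(out) <- "dep_comparison"
  out
}

#' @export
print.dep_comparison <- function(x, ...) {
  cat(sprintf("Unpaired two-tailed t-test (%s)%s: %s vs %s\n", x$variant,
              if (nzchar(x$parameter)) paste0(" on ", x$parameter) else "",
              x$group_a, x$group_b))
  if (x$status == "undefined") {
    cat("  degenerate: zero variance in both groups with equal means\n")
  } else {
    cat(sprintf("  t = %.4g, df = %.4g, p = %.4g %s\n",
                x$t_statistic, x$df, x$p_value, x$stars))
  }
  invisible(x)
}

#' All pairwise group comparisons on the per-biological estimates
#'
#' @param estimates the table from [aggregate_repeats()].
#' @param parameters columns to test.
#' @param variant `"pooled"` or `"welch"`.
#' @return Data frame: one row per group pair and parameter with t,
#'   df, p (4 significant figures in the printed CSV), stars, status.
#' @export
compare_all_groups <- function(estimates,
                               parameters = c("radius_um", "g_eff", "c_eff_mF",
                                              "sigma_cyt", "c_whole_pF"),
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  groups <- unique(estimates$group)
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  rows <- list()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      for (p in parameters) {
        cmp <- compare_groups(estimates[[p]][estimates$group == groups[i]],
                              estimates[[p]][estimates$group == groups[j]],
                              variant = variant, parameter = p,
                              group_a = groups[i], group_b = groups[j])
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = groups[i], group_b = groups[j], parameter = p,
          t_statistic = cmp$t_statistic, df = cmp$df, p_value = cmp$p_value,
          stars = if (is.na(cmp$stars)) "" else cmp$stars,
          variant = variant, status = cmp$status,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Score parameter recovery against a ground-truth manifest
#'
#' Relative error of each group's fitted mean against the generating
#' mean (the mean of the true per-biological-repeat parameters in the
#' manifest).
#'
#' @param summaries group summary table from [summarize_group()].
#' @param manifest manifest data frame from [cohort_manifest()] (or
#'   `manifest.csv` read back from disk).
#' @return Data frame: group, parameter, fitted mean, true mean,
#'   relative error.
#' @export
score_recovery <- function(summaries, manifest) {
  if (is.null(manifest) || nrow(manifest) == 0L) {
    stop("manifest is empty", call. = FALSE)
  }
  if (!setequal(summaries$group, unique(manifest$group))) {
    stop("group labels in summaries and manifest do not match", call. = FALSE)
  }
  params <- c(radius_um = "radius_um", g_eff = "g_eff",
              c_eff_mF = "c_eff_mF", sigma_cyt = "sigma_cyt")
  rows <- list()
  for (g in summaries$group) {
    mf <- manifest[manifest$group == g, , drop = FALSE]
    mf <- mf[!duplicated(mf$biological_id), , drop = FALSE]  # per-bio truth
    for (p in names(params)) {
      true_mean <- mean(mf[[params[[p]]]])
      fitted_mean <- summaries[[paste0(p, "_mean")]][summaries$group == g]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, fitted_mean = fitted_mean,
        true_mean = true_mean,
        relative_error = (fitted_mean - true_mean) / true_mean,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full DEP study pipeline on synthetic cohorts
#'
#' Generates (or accepts) cohorts, fits every spectrum, applies the
#' Pearson-R exclusion rule, aggregates technical repeats into
#' per-biological estimates, summarises groups, runs all pairwise
#' unpaired two-tailed t-tests, and scores parameter recovery against
#' the ground-truth manifest.
#'
#' @param specs a list of [cohort_spec()] objects, or pre-generated
#'   `dep_cohort` objects.
#' @param medium a [dep_medium()] object.
#' @param frequencies frequency grid for simulation, Hz.
#' @param control a [dep_fit_control()] list.
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return An object of class `dep_study`: list with `fits`,
#'   `estimates`, `summaries`, `comparisons`, `recovery`, `excluded`
#'   (the excluded fits with their R values) and the inputs.
#' @export
#' @examples
#' \donttest{
#' presets <- table_presets(seed = 11)
#' study <- run_study(presets[c("equine_control", "equine_acute")])
#' study$summaries
#' }
run_study <- function(specs, medium = dep_medium(),
                      frequencies = default_frequencies(),
                      control = dep_fit_control(),
                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  cohorts <- lapply(specs, function(s) {
    if (inherits(s, "dep_cohort")) s
    else generate_cohort(s, medium = medium, frequencies = frequencies)
  })
  fits <- do.call(rbind, lapply(cohorts, fit_cohort,
                                medium = medium, control = control))
  estimates <- aggregate_repeats(fits)
  summaries <- summarize_group(estimates, fits)
  comparisons <- if (length(unique(estimates$group)) >= 2L) {
    compare_all_groups(estimates, variant = variant)
  } else {
    NULL
  }
  manifest <- cohort_manifest(cohorts)
  structure(list(fits = fits, estimates = estimates, summaries = summaries,
                 comparisons = comparisons,
                 recovery = score_recovery(summaries, manifest),
                 excluded = fits[!fits$accepted,
                                 c("group", "biological_id", "technical_id",
                                   "pearson_r", "status")],
                 manifest = manifest, medium = medium, control = control,
                 variant = variant),
            class = "dep_study")
}

#' @export
print.dep_study <- function(x, ...) {
  cat("DEP study\n")
  cat(sprintf("  groups: %s\n", paste(x$summaries$group, collapse = ", ")))
  cat(sprintf("  fits: %d (%d excluded by the R > %.2g rule)\n",
              nrow(x$fits), nrow(x$excluded),
              x$control$accept_threshold))
  cat("\nGroup summaries (mean +/- SD):\n")
  s <- x$summaries
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s r %.3g+/-%.2g um | G_eff %.4g+/-%.3g S/m^2 | C_eff %.3g+/-%.2g mF/m^2 | sig_cyt %.3g+/-%.2g S/m | C %.3g+/-%.2g pF\n",
                s$group[i], s$radius_um_mean[i], s$radius_um_sd[i],
                s$g_eff_mean[i], s$g_eff_sd[i],
                s$c_eff_mF_mean[i], s$c_eff_mF_sd[i],
                s$sigma_cyt_mean[i], s$sigma_cyt_sd[i],
                s$c_whole_pF_mean[i], s$c_whole_pF_sd[i]))
  }
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits `group_summaries.csv`, `comparisons.csv`, `recovery.json` and
#' `excluded_fits.csv`.
#'
#' @param study a `dep_study` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dep_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$summaries, file.path(dir, "group_summaries.csv"),
                   row.names = FALSE)
  if (!is.null(study$comparisons)) {
    cmp <- study$comparisons
    cmp$p_value <- signif(cmp$p_value, 4)
    utils::write.csv(cmp, file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  jsonlite::write_json(study$recovery, file.path(dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.csv(study$excluded, file.path(dir, "excluded_fits.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a study configuration file
#'
#' JSON with any of: `medium_conductivity`, `medium_rel_permittivity`,
#' `g_eff_bounds`, `c_eff_bounds`, `sigma_cyt_bounds`, `fit_offset`,
#' `accept_threshold`, `frequency_grid` (Hz array) or `f_min`/`f_max`/
#' `n_frequencies`, `t_test_variant`, `seed`. Missing entries fall back
#' to package defaults.
#'
#' @param path JSON path.
#' @return List with `medium`, `control`, `frequencies`, `variant`,
#'   `seed`.
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  medium <- dep_medium(
    conductivity = cfg$medium_conductivity %||% 0.15,
    rel_permittivity = cfg$medium_rel_permittivity %||% 78)
  control <- dep_fit_control(
    g_eff_bounds = cfg$g_eff_bounds %||% c(0, 1e5),
    c_eff_bounds = cfg$c_eff_bounds %||% c(1e-3, 1e-1),
    sigma_cyt_bounds = cfg$sigma_cyt_bounds %||% c(0.01, 2),
    fit_offset = cfg$fit_offset %||% FALSE,
    accept_threshold = cfg$accept_threshold %||% 0.9)
  frequencies <- if (!is.null(cfg$frequency_grid)) {
    as.numeric(cfg$frequency_grid)
  } else {
    default_frequencies(n = cfg$n_frequencies %||% 20L,
                        f_min = cfg$f_min %||% 1e3,
                        f_max = cfg$f_max %||% 4.5e7)
  }
  list(medium = medium, control = control, frequencies = frequencies,
       variant = cfg$t_test_variant %||% "pooled",
       seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
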