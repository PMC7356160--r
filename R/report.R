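#' General-population reference Cd intakes
#'
#' Market-basket estimates of daily Cd intake by the general Japanese
#' population (ug/day, split into rice and other foods) used for
#' fold-ratio comparisons.
#'
#' @return `data.frame` with `year`, `rice_ug_day`, `other_ug_day`,
#'   `total_ug_day`.
#' @export
reference_intakes <- function() {
  utils::read.csv(system.file("extdata", "jp_reference_intakes.csv",
                              package = "cdexposure"))
}

#' Run the intake assessment and write report tables
#'
#' Orchestrates the full individual-food-analysis stage: reads (or takes)
#' a subject table, fits [cd_exposure()], and writes CSV reports - the
#' per-subject intakes, the per-subgroup cohort summary, the TWI exceedance
#' partition, the age-stratified weekly intakes, a unit-width histogram-bin
#' table of weekly intake, and the exclusion/unmapped logs.
#'
#' @param subjects subject `data.frame` or path to a subject CSV.
#' @param output_dir directory for the report files (created if needed).
#' @param concentrations,mapping,twi,mass_change_factors passed to
#'   [cd_exposure()].
#' @return the `cd_exposure` fit, invisibly; report paths in attribute
#'   `files`.
#' @export
run_intake <- function(subjects, output_dir,
                       concentrations = cd_concentrations(),
                       mapping = default_mapping(), twi = 7,
                       mass_change_factors = NULL) {
  if (is.character(subjects)) subjects <- read_subjects(subjects)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- cd_exposure(subjects, concentrations = concentrations,
                     mapping = mapping, twi = twi,
                     mass_change_factors = mass_change_factors)
  sm <- summary(fit)
  w <- fit$intake$weekly_ug_kg_bw
  hist_tab <- as.data.frame(table(cut(w, breaks = seq(0, ceiling(max(w)) + 1,
                                                      by = 1), right = FALSE)))
  names(hist_tab) <- c("bin_ug_kg_bw_week", "n")

  files <- c(per_subject = "per_subject_intake.csv",
             subgroups = "subgroup_summary.csv",
             exceedance = "exceedance.csv",
             by_age = "age_stratified.csv",
             histogram = "weekly_intake_histogram.csv",
             exclusions = "exclusions.csv")
  files <- stats::setNames(file.path(output_dir, files), names(files))
  utils::write.csv(fit$intake, files["per_subject"], row.names = FALSE)
  utils::write.csv(round_for_report(sm$subgroups), files["subgroups"],
                   row.names = FALSE)
  utils::write.csv(sm$exceedance, files["exceedance"], row.names = FALSE)
  utils::write.csv(round_for_report(sm$by_age), files["by_age"],
                   row.names = FALSE)
  utils::write.csv(hist_tab, files["histogram"], row.names = FALSE)
  utils::write.csv(fit$exclusions, files["exclusions"], row.names = FALSE)
  if (length(fit$unmapped))
    writeLines(fit$unmapped, file.path(output_dir, "unmapped_items.txt"))
  attr(fit, "files") <- files
  invisible(fit)
}

# one-decimal presentation columns alongside full precision
round_for_report <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "n"
  for (col in names(tab)[num]) tab[[paste0(col, "_1dp")]] <- round(tab[[col]], 1)
  tab
}

#' Run the Monte Carlo weekly-intake simulation
#'
#' Fits a lognormal model to weekly intakes - either by maximum likelihood
#' from a cohort (after iterative Grubbs screening of log weekly intakes)
#' or by quantile matching from a printed (q25, median, q75) triple - then
#' draws `n_reps` seeded repetitions and writes a simulation summary CSV
#' (median, 5th-95th percentiles, range, n_reps, seed).
#'
#' @param source a `cd_exposure` fit, a numeric vector of weekly intakes,
#'   or a length-3 numeric `c(q25, median, q75)` of summary quantiles.
#' @param output_dir directory for `simulation_summary.csv`; `NULL` skips
#'   writing.
#' @param n_reps number of Monte Carlo repetitions.
#' @param seed integer seed (recorded in the report).
#' @param grubbs_alpha significance level of the outlier screen; `NA`
#'   disables screening.
#' @return list with `fit` (`cd_lognormal`), `draws`, `summary`
#'   (see [summarize_simulation()]) and `outliers` (removed positions).
#' @export
run_simulation <- function(source, output_dir = NULL, n_reps = 10000,
                           seed = 1L, grubbs_alpha = 0.05) {
  outliers <- integer(0)
  if (inherits(source, "cd_exposure"))
    source <- source$intake$weekly_ug_kg_bw
  if (is.numeric(source) && length(source) == 3) {
    # a length-3 vector is read as printed summary quantiles (q25, med, q75)
    fit <- fit_lognormal_quantiles(source[1], source[2], source[3])
  } else {
    weekly <- as.numeric(source)
    if (!is.na(grubbs_alpha) && length(weekly) >= 3) {
      scr <- grubbs_iterative(log(weekly), alpha = grubbs_alpha)
      outliers <- scr$outliers
      if (length(outliers)) weekly <- weekly[-outliers]
      if (length(outliers))
        message(length(outliers), " outlier(s) excluded before fitting")
    }
    fit <- fit_lognormal_mle(weekly)
  }
  draws <- simulate(fit, nsim = n_reps, seed = seed)
  sm <- summarize_simulation(draws)
  sm$seed <- seed
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(round_for_report(sm[1:5]),
                           sm["seed"], mu = fit$mu, sigma = fit$sigma),
                     file.path(output_dir, "simulation_summary.csv"),
                     row.names = FALSE)
  }
  list(fit = fit, draws = draws, summary = sm, outliers = outliers)
}

#' Fold-ratio comparison against general-population intakes
#'
#' Ratios of cohort median Cd intakes (rice / other foods / total, ug/day)
#' to a general-population reference, rounded to one decimal for
#' presentation with full-precision companions.
#'
#' @param cohort_medians named numeric: `rice`, `other` (ug/day) for one
#'   cohort.
#' @param reference one row of [reference_intakes()] (or a list with
#'   `rice_ug_day`, `other_ug_day`).
#' @param output_dir optional directory for `fold_ratios.csv`.
#' @return `data.frame` with components, reference values and fold ratios.
#' @export
run_compare <- function(cohort_medians, reference, output_dir = NULL) {
  ref <- c(rice = as.numeric(reference$rice_ug_day),
           other = as.numeric(reference$other_ug_day))
  if (any(ref == 0)) stop("zero reference intake")
  coh <- c(rice = as.numeric(cohort_medians["rice"]),
           other = as.numeric(cohort_medians["other"]))
  out <- data.frame(
    component = c("rice_and_rice_products", "other_foods", "total"),
    cohort_ug_day = c(coh, sum(coh)),
    reference_ug_day = c(ref, sum(ref)),
    fold_ratio = c(coh / ref, sum(coh) / sum(ref)))
  out$fold_ratio_1dp <- round(out$fold_ratio, 1)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(output_dir, "fold_ratios.csv"),
                     row.names = FALSE)
  }
  out
}
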