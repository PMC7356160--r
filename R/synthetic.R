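# truncated-normal sampling by inversion (deterministic draw count)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

# age bands: printed stratum counts, means and sds per area
AGE_BANDS_A <- data.frame(
  lo = c(20, 30, 40, 50, 60, 70), hi = c(29, 39, 49, 59, 69, 79),
  count = c(27, 27, 109, 213, 278, 58),
  mean = c(25.0, 35.0, 45.4, 54.6, 64.6, 72.8),
  sd = c(3.0, 3.2, 2.9, 2.9, 2.8, 2.2))
AGE_BANDS_B <- data.frame(
  lo = c(30, 40, 50, 60, 70), hi = c(39, 49, 59, 69, 82),
  count = c(14, 85, 151, 143, 39),
  mean = c(36.8, 45.8, 54.6, 63.9, 73.1),
  sd = c(1.5, 2.7, 2.8, 2.8, 2.8))

# fixed diet shares of the non-rice Cd component across representative
# questionnaire items (proportions follow the relative subgroup medians of
# the study cohorts: cereals/tubers, soybeans, vegetables, mushrooms,
# seafood, others)
NONRICE_SHARES <- c(potato = 0.112, miso = 0.159,
                    leafy_green_vegetables = 0.290, mushrooms = 0.131,
                    oysters = 0.285, manju = 0.023)

#' Synthetic cohort parameters
#'
#' Parameter sets for [generate_cohort()]. The packaged presets `"area_A"`
#' and `"area_B"` encode the study conditions of the two surveyed areas:
#' anthropometric and intake distributions truncated to the printed ranges,
#' area rice Cd geometric means with a log-sd derived from the printed
#' fraction of rice above the 0.4 mg/kg safety standard, a cooked-rice
#' mass-change factor, and a single lognormal non-rice intake component
#' whose parameters were calibrated (see [calibrate_nonrice_component()])
#' so the generated weekly-intake distribution matches the printed cohort
#' median and quartiles.
#'
#' @param preset `"area_A"` or `"area_B"`.
#' @param n cohort size override (defaults to the study size: 712 / 432).
#' @param ... named overrides of individual parameter fields.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(preset = c("area_A", "area_B"), n = NULL, ...) {
  preset <- match.arg(preset)
  p <- if (preset == "area_A") {
    list(area = "A", n = 712,
         age_bands = transform(AGE_BANDS_A, prop = count / sum(count)),
         height = c(mean = 152.0, sd = 6.2, lo = 130, hi = 180),
         weight = c(mean = 54.5, sd = 8.0, lo = 34, hi = 92),
         energy = c(mean = 1933.7, sd = 463.7, lo = 1000, hi = 3440),
         rice_intake = c(mean = 371.8, sd = 118.9, lo = 78.6, hi = 1120),
         rice_cd_log_gm = log(0.158), rice_cd_log_sd = 0.667,
         brown_rice_prop = 0.05, n_missing_rice_cd = 1,
         nonrice_mu = 3.2392, nonrice_sigma = 0.4068,
         nonrice_shares = NONRICE_SHARES,
         mass_change_factors = c(rice = 0.476))
  } else {
    list(area = "B", n = 432,
         age_bands = transform(AGE_BANDS_B, prop = count / sum(count)),
         height = c(mean = 152.8, sd = 5.9, lo = 132, hi = 169),
         weight = c(mean = 55.5, sd = 8.5, lo = 33, hi = 94),
         energy = c(mean = 1923.8, sd = 459.0, lo = 1047, hi = 3451),
         rice_intake = c(mean = 359.0, sd = 105.3, lo = 30, hi = 880),
         rice_cd_log_gm = log(0.109), rice_cd_log_sd = 0.827,
         brown_rice_prop = 0.05, n_missing_rice_cd = 0,
         nonrice_mu = 3.2776, nonrice_sigma = 0.3942,
         nonrice_shares = NONRICE_SHARES,
         mass_change_factors = c(rice = 0.476))
  }
  dots <- list(...)
  p[names(dots)] <- dots
  if (!is.null(n)) p$n <- n
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  if (!is.numeric(p$n) || p$n < 1) stop("n must be a positive count")
  for (f in c("height", "weight", "energy", "rice_intake")) {
    v <- p[[f]]
    if (v["sd"] <= 0) stop(f, ": sd must be positive")
    if (v["lo"] >= v["hi"]) stop(f, ": truncation lo must be below hi")
  }
  if (abs(sum(p$age_bands$prop) - 1) > 1e-9)
    stop("age band proportions must sum to 1")
  if (p$rice_cd_log_sd <= 0) stop("rice_cd_log_sd must be positive")
  if (p$nonrice_sigma <= 0) stop("nonrice_sigma must be positive")
  invisible(p)
}

#' Generate a synthetic cohort
#'
#' Draws a subject table with the statistical structure the exposure
#' assessment assumes: truncated-normal anthropometrics, energy and rice
#' intake; stratified ages; lognormal individual rice Cd; and a lognormal
#' non-rice daily Cd component distributed across six representative
#' questionnaire items in fixed shares (grams derived by dividing each
#' item's Cd share by its effective concentration, so the intake engine
#' reproduces the intended component exactly). Deterministic under `seed`.
#'
#' The cohort's mass-change factor table (cooked-rice conversion) is
#' attached as attribute `mass_change_factors` and picked up by
#' [cd_exposure()].
#'
#' @param params a `cohort_params` object.
#' @param seed integer seed.
#' @param concentrations,mapping tables used to resolve the per-item
#'   concentrations for the gram split.
#' @return a subject `data.frame` (see [read_subjects()]).
#' @export
generate_cohort <- function(params, seed,
                            concentrations = cd_concentrations(),
                            mapping = default_mapping()) {
  validate_cohort_params(params)
  set.seed(seed)
  n <- params$n
  bands <- params$age_bands
  band <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$prop)
  age <- rtrunc_norm(n, bands$mean[band], bands$sd[band],
                     bands$lo[band], bands$hi[band])
  height <- rtrunc_norm(n, params$height["mean"], params$height["sd"],
                        params$height["lo"], params$height["hi"])
  weight <- rtrunc_norm(n, params$weight["mean"], params$weight["sd"],
                        params$weight["lo"], params$weight["hi"])
  energy <- rtrunc_norm(n, params$energy["mean"], params$energy["sd"],
                        params$energy["lo"], params$energy["hi"])
  rice_g <- rtrunc_norm(n, params$rice_intake["mean"],
                        params$rice_intake["sd"],
                        params$rice_intake["lo"], params$rice_intake["hi"])
  rice_cd <- stats::rlnorm(n, params$rice_cd_log_gm, params$rice_cd_log_sd)
  brown <- stats::runif(n) < params$brown_rice_prop
  nonrice_ug <- stats::rlnorm(n, params$nonrice_mu, params$nonrice_sigma)

  shares <- params$nonrice_shares
  shares <- shares / sum(shares)
  conc <- vapply(names(shares), function(it)
    resolve_concentration(mapping[[it]], concentrations), numeric(1))
  grams <- outer(nonrice_ug, shares / conc)   # g/day per item

  subjects <- data.frame(
    id = sprintf("%s%04d", params$area, seq_len(n)),
    area = params$area,
    age = round(age, 1), height_cm = round(height, 1),
    weight_kg = round(weight, 1), energy_kcal = energy,
    rice_cd_mg_per_kg = rice_cd, brown_rice = brown,
    rice = rice_g, stringsAsFactors = FALSE)
  subjects <- cbind(subjects, as.data.frame(grams))
  k <- min(params$n_missing_rice_cd, n)
  if (k > 0) subjects$rice_cd_mg_per_kg[seq_len(k)] <- NA_real_
  attr(subjects, "mass_change_factors") <- params$mass_change_factors
  subjects
}

#' Calibrate the non-rice intake component
#'
#' Adjusts the lognormal non-rice component `(mu, sigma)` by a damped
#' stochastic fixed-point search so the generated cohort's weekly-intake
#' median and quartiles match target quantiles. The search holds the
#' generator seed fixed across iterations, updating `mu` by the log ratio
#' of target to achieved median and `sigma` by the ratio of target to
#' achieved log interquartile spread.
#'
#' Because the rice component (individual rice Cd times rice intake)
#' contributes its own dispersion, very tight target spreads may be
#' unattainable; on non-convergence the error message reports the best
#' achieved quantiles (or set `on_fail = "best"` to return them).
#'
#' @param target_median,target_q25,target_q75 target weekly-intake
#'   quantiles (ug/kg BW/week), strictly increasing.
#' @param params starting `cohort_params`.
#' @param tol relative tolerance on all three quantiles.
#' @param max_iter iteration cap.
#' @param n_sim cohort size used during the search.
#' @param seed generator seed held fixed across iterations.
#' @param on_fail `"error"` (default) or `"best"`.
#' @return updated `cohort_params` with attribute `achieved` (the
#'   quantiles of the final calibration cohort).
#' @export
calibrate_nonrice_component <- function(target_median, target_q25, target_q75,
                                        params, tol = 0.03, max_iter = 40,
                                        n_sim = 4000, seed = 1L,
                                        on_fail = c("error", "best")) {
  on_fail <- match.arg(on_fail)
  if (!(target_q25 > 0 && target_q25 < target_median &&
        target_median < target_q75))
    stop("targets must satisfy 0 < q25 < median < q75")
  p <- params
  p$n <- n_sim
  targets <- c(q25 = target_q25, median = target_median, q75 = target_q75)
  best <- NULL; best_err <- Inf
  for (iter in seq_len(max_iter)) {
    cohort <- generate_cohort(p, seed = seed)
    fit <- suppressWarnings(cd_exposure(cohort))
    qhat <- stats::quantile(fit$intake$weekly_ug_kg_bw, c(0.25, 0.5, 0.75),
                            type = 7, names = FALSE)
    err <- max(abs(qhat / targets - 1))
    if (err < best_err) {
      best_err <- err
      best <- list(mu = p$nonrice_mu, sigma = p$nonrice_sigma, qhat = qhat)
    }
    if (err < tol) break
    p$nonrice_mu <- p$nonrice_mu + 1.2 * log(target_median / qhat[2])
    spread_ratio <- log(target_q75 / target_q25) / log(qhat[3] / qhat[1])
    p$nonrice_sigma <- max(0.05, p$nonrice_sigma * spread_ratio^1.2)
  }
  out <- params
  out$nonrice_mu <- best$mu
  out$nonrice_sigma <- best$sigma
  if (best_err >= tol && on_fail == "error")
    stop(sprintf(paste0("calibration did not converge (tol %.3g): best ",
                        "achieved q25/median/q75 = %.3f/%.3f/%.3f vs ",
                        "targets %.3f/%.3f/%.3f"),
                 tol, best$qhat[1], best$qhat[2], best$qhat[3],
                 target_q25, target_median, target_q75))
  attr(out, "achieved") <- stats::setNames(best$qhat,
                                           c("q25", "median", "q75"))
  out
}

#' Implant artificial outliers into a cohort
#'
#' Scales `k` subjects' intakes so their weekly Cd intake equals
#' `multiplier` times the cohort maximum, for end-to-end testing of the
#' outlier screen. `k = 0` returns the cohort unchanged.
#'
#' @param subjects subject `data.frame`.
#' @param k number of outliers (first `k` subjects are scaled).
#' @param multiplier target weekly intake as a multiple of the cohort max.
#' @return the modified cohort, with the implanted ids in attribute
#'   `implanted`.
#' @export
implant_outliers <- function(subjects, k, multiplier = 5) {
  if (k < 0) stop("k must be nonnegative")
  if (k > nrow(subjects)) stop("k exceeds cohort size")
  if (k == 0) { attr(subjects, "implanted") <- character(0); return(subjects) }
  fit <- suppressWarnings(cd_exposure(subjects, apply_filters = FALSE))
  weekly <- fit$intake$weekly_ug_kg_bw
  target <- multiplier * max(weekly)
  items <- intake_items(subjects)
  for (i in seq_len(k)) {
    subjects[i, items] <- subjects[i, items] * (target / weekly[i])
  }
  attr(subjects, "implanted") <- subjects$id[seq_len(k)]
  subjects
}
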