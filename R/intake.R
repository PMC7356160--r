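SUBJECT_FIXED_COLS <- c("id", "area", "age", "height_cm", "weight_kg",
                        "energy_kcal", "rice_cd_mg_per_kg", "brown_rice")

#' Read / write a subject table
#'
#' A subject table holds one row per participant: `id, area, age, height_cm,
#' weight_kg, energy_kcal, rice_cd_mg_per_kg, brown_rice`, followed by one
#' column per questionnaire item with intake in g/day.
#'
#' @param path CSV path.
#' @return `read_subjects`: the subject `data.frame`.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  subj <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(SUBJECT_FIXED_COLS, names(subj))
  if (length(missing_cols))
    stop("subject table lacks columns: ", paste(missing_cols, collapse = ", "))
  subj$brown_rice <- as.logical(subj$brown_rice)
  items <- intake_items(subj)
  neg <- vapply(subj[items], function(v) any(v < 0, na.rm = TRUE), logical(1))
  if (any(neg))
    stop("negative intake in column(s): ", paste(items[neg], collapse = ", "))
  if (any(subj$weight_kg <= 0, na.rm = TRUE)) stop("non-positive body weight")
  subj
}

#' @rdname read_subjects
#' @param subjects subject `data.frame`.
#' @return `write_subjects`: the path, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# names of the per-item intake columns
intake_items <- function(subjects) setdiff(names(subjects), SUBJECT_FIXED_COLS)

#' Apply the cohort exclusion filters
#'
#' Removes subjects with extremely low or high reported energy intake
#' (at or below `energy_lo`, at or above `energy_hi` kcal/day) and subjects
#' reporting zero rice consumption, logging a reason per exclusion. The
#' filter is idempotent.
#'
#' @param subjects subject `data.frame`.
#' @param energy_lo,energy_hi exclusion bounds in kcal/day (excluded when
#'   `energy <= energy_lo` or `energy >= energy_hi`).
#' @param rice_item name of the rice intake column.
#' @return list with `kept` (filtered subject table) and `log` (a
#'   `data.frame` of excluded ids and reasons).
#' @export
apply_exclusions <- function(subjects, energy_lo = 1000, energy_hi = 3500,
                             rice_item = "rice") {
  reason <- rep(NA_character_, nrow(subjects))
  low <- subjects$energy_kcal <= energy_lo
  high <- subjects$energy_kcal >= energy_hi
  reason[low] <- "energy_low"
  reason[high] <- "energy_high"
  if (rice_item %in% names(subjects)) {
    zero_rice <- is.na(reason) & subjects[[rice_item]] == 0
    reason[zero_rice] <- "zero_rice"
  }
  drop <- !is.na(reason)
  list(kept = subjects[!drop, , drop = FALSE],
       log = data.frame(id = subjects$id[drop], reason = reason[drop],
                        stringsAsFactors = FALSE))
}

#' Weekly Cd intake per body weight
#'
#' @param total daily Cd intake in ug/day.
#' @param weight body weight in kg (> 0).
#' @return weekly intake in ug/kg BW/week: `7 * total / weight`.
#' @export
weekly_per_bw <- function(total, weight) {
  if (any(weight <= 0)) stop("body weight must be positive")
  7 * total / weight
}

# Resolve per-item effective concentrations once for the whole cohort.
# Subject-independent items give one number; RICE_INDIVIDUAL components are
# returned separately as a per-gram rice weight so the subject's own rice Cd
# can be applied vectorised.
.resolve_item_concentrations <- function(items, rules, table,
                                         rule_censored = "zero") {
  fixed <- numeric(length(items))
  rice_weight <- numeric(length(items))   # weight on RICE_INDIVIDUAL
  mcf <- rep(1, length(items))
  unmapped <- character(0)
  for (i in seq_along(items)) {
    rule <- rules[[items[i]]]
    if (is.null(rule)) {
      unmapped <- c(unmapped, items[i])
      next
    }
    mcf[i] <- rule$mass_change_factor
    if (rule$excluded) next
    for (cm in rule$components) {
      if (identical(cm$source, "RICE_INDIVIDUAL")) {
        rice_weight[i] <- rice_weight[i] + cm$weight
      } else if (!is.null(cm$average_of)) {
        fixed[i] <- fixed[i] + cm$weight *
          mean(vapply(cm$average_of, function(it)
            pooled_mean(table, it, rule_censored), numeric(1)))
      } else {
        fixed[i] <- fixed[i] + cm$weight *
          pooled_mean(table, cm$source, rule_censored)
      }
    }
  }
  list(fixed = fixed, rice_weight = rice_weight, mcf = mcf,
       unmapped = unmapped,
       subgroup = vapply(items, function(it) {
         rule <- rules[[it]]
         if (is.null(rule) || rule$excluded) return(NA_character_)
         # reporting group of the dominant component
         refs <- referenced_items(rule)
         if ("RICE_INDIVIDUAL" %in% refs) return("rice_and_rice_products")
         sg <- table$subgroup[match(refs[1], table$item)]
         .reporting_group(sg)
       }, character(1)))
}

#' Per-subject daily Cd intake
#'
#' Computes one subject's daily Cd intake: for each questionnaire item,
#' contribution (ug/day) = effective concentration (ug/g) x intake (g/day)
#' x mass-change factor, accumulated into the seven reporting subgroups
#' (seaweed, fish and shellfish merge into seafood; livestock and
#' miscellaneous foods into others; fruit is excluded). Rice uses the
#' subject's own rice Cd - reduced by 10% for brown rice - or the cohort
#' geometric mean when missing.
#'
#' For composite items (e.g. barley rice = 70% rice + 30% wheat flour) each
#' component accrues to its own subgroup.
#'
#' @param subject one-row subject `data.frame`.
#' @param rules `dhq_mapping` rule list.
#' @param table concentration record `data.frame`.
#' @param cohort_rice_gm fallback rice Cd GM (mg/kg).
#' @param mass_change_factors optional named numeric vector of raw-mass per
#'   reported-mass factors, multiplied onto the mapping's own factors
#'   (names are questionnaire items, e.g. `c(rice = 0.476)` for cooked
#'   rice reported as served).
#' @param twi tolerable weekly intake threshold in ug/kg BW/week.
#' @param brown_rice_factor polished-rice equivalence factor for brown rice.
#' @return a one-row `data.frame`: `id`, the seven subgroup intakes
#'   (ug/day), `total_ug_day`, `weekly_ug_kg_bw`, `exceeds_twi`.
#' @export
subject_daily_intake <- function(subject, rules, table,
                                 cohort_rice_gm = NULL,
                                 mass_change_factors = NULL,
                                 twi = 7, brown_rice_factor = 0.9) {
  res <- .cohort_intakes(subject, rules, table, cohort_rice_gm,
                         mass_change_factors, twi, brown_rice_factor)
  res$intake
}

# Vectorised engine shared by subject_daily_intake() and cd_exposure().
.cohort_intakes <- function(subjects, rules, table, cohort_rice_gm = NULL,
                            mass_change_factors = NULL, twi = 7,
                            brown_rice_factor = 0.9, warn_unmapped = TRUE) {
  items <- intake_items(subjects)
  rc <- .resolve_item_concentrations(items, rules, table)
  if (warn_unmapped && length(rc$unmapped))
    warning("questionnaire item(s) without mapping rule contribute zero: ",
            paste(rc$unmapped, collapse = ", "))
  mcf <- rc$mcf
  if (!is.null(mass_change_factors)) {
    idx <- match(items, names(mass_change_factors))
    mcf <- mcf * ifelse(is.na(idx), 1, mass_change_factors[idx])
  }
  n <- nrow(subjects)
  intake_mat <- as.matrix(subjects[items])
  intake_mat[is.na(intake_mat)] <- 0
  intake_mat <- sweep(intake_mat, 2, mcf, `*`)

  # per-subject rice Cd (GM substitution, brown-rice adjustment)
  rice_cd <- subjects$rice_cd_mg_per_kg
  if (any(is.na(rice_cd))) {
    if (is.null(cohort_rice_gm) || any(is.na(cohort_rice_gm)))
      stop("subject(s) lack rice Cd and no cohort geometric mean is available: ",
           paste(subjects$id[is.na(rice_cd)], collapse = ", "))
    gm <- if (length(cohort_rice_gm) > 1)
      cohort_rice_gm[subjects$area] else rep(cohort_rice_gm, n)
    rice_cd[is.na(rice_cd)] <- gm[is.na(rice_cd)]
  }
  rice_cd <- ifelse(subjects$brown_rice %in% TRUE,
                    brown_rice_factor * rice_cd, rice_cd)

  groups <- matrix(0, n, length(REPORTING_SUBGROUPS),
                   dimnames = list(NULL, REPORTING_SUBGROUPS))
  for (j in seq_along(items)) {
    contrib_fixed <- intake_mat[, j] * rc$fixed[j]
    contrib_rice <- intake_mat[, j] * rc$rice_weight[j] * rice_cd
    if (rc$rice_weight[j] > 0)
      groups[, "rice_and_rice_products"] <-
        groups[, "rice_and_rice_products"] + contrib_rice
    if (rc$fixed[j] > 0) {
      sg <- rc$subgroup[j]
      # composite rice items route their non-rice share to the source group
      if (rc$rice_weight[j] > 0) {
        rule <- rules[[items[j]]]
        nonrice <- setdiff(referenced_items(rule), "RICE_INDIVIDUAL")
        sg <- .reporting_group(table$subgroup[match(nonrice[1], table$item)])
      }
      if (!is.na(sg)) groups[, sg] <- groups[, sg] + contrib_fixed
    }
  }
  total <- rowSums(groups)
  weekly <- weekly_per_bw(total, subjects$weight_kg)
  intake <- data.frame(id = subjects$id, area = subjects$area,
                       age = subjects$age, weight_kg = subjects$weight_kg,
                       groups, total_ug_day = total,
                       weekly_ug_kg_bw = weekly,
                       exceeds_twi = weekly >= twi,
                       stringsAsFactors = FALSE)
  list(intake = intake, unmapped = rc$unmapped)
}

#' Classify TWI exceedance
#'
#' Partitions weekly intakes into below-threshold and at-or-above-threshold
#' bins (the boundary value counts as exceeding), with percentages to one
#' decimal.
#'
#' @param weekly weekly intakes in ug/kg BW/week.
#' @param threshold tolerable weekly intake (default 7 ug/kg BW/week).
#' @return `data.frame` with `bin`, `n`, `pct`.
#' @export
classify_exceedance <- function(weekly, threshold = 7) {
  if (threshold <= 0) stop("threshold must be positive")
  above <- sum(weekly >= threshold)
  below <- length(weekly) - above
  data.frame(
    bin = c(sprintf("<%g", threshold), sprintf(">=%g", threshold)),
    n = c(below, above),
    pct = round(100 * c(below, above) / length(weekly), 1),
    stringsAsFactors = FALSE)
}

quartile_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(x), median = q[2], q25 = q[1], q75 = q[3],
             min = min(x), max = max(x))
}

#' Cohort summary of an intake quantity
#'
#' Medians with 25th/75th percentiles and ranges, overall and within decade
#' age strata (20-29, ..., 70+). Quartiles use linear interpolation of
#' order statistics (quantile type 7). Empty strata are reported with
#' `n = 0` and `NA` statistics.
#'
#' @param values numeric vector (e.g. weekly intakes).
#' @param age optional ages for stratification.
#' @param age_breaks left endpoints of the decade bins.
#' @return `data.frame` of summaries, one row overall plus one per stratum
#'   when `age` is given.
#' @export
cohort_summary <- function(values, age = NULL,
                           age_breaks = c(20, 30, 40, 50, 60, 70)) {
  if (!length(values)) stop("no values to summarise")
  out <- cbind(stratum = "all", quartile_summary(values))
  if (!is.null(age)) {
    labs <- c(paste(age_breaks[-length(age_breaks)],
                    age_breaks[-1] - 1, sep = "-"),
              paste0(age_breaks[length(age_breaks)], "+"))
    idx <- findInterval(age, c(age_breaks, Inf))
    idx[idx == 0] <- NA
    for (k in seq_along(labs)) {
      v <- values[!is.na(idx) & idx == k]
      row <- if (length(v)) quartile_summary(v)
             else data.frame(n = 0, median = NA_real_, q25 = NA_real_,
                             q75 = NA_real_, min = NA_real_, max = NA_real_)
      out <- rbind(out, cbind(stratum = labs[k], row))
    }
  }
  rownames(out) <- NULL
  out
}

#' Fit the dietary Cd exposure assessment to a cohort
#'
#' The central fitting function: applies the exclusion filters, resolves
#' every questionnaire item's effective Cd concentration through the
#' mapping, multiplies by individual intakes, accumulates daily intake by
#' subgroup, and converts to weekly intake per body weight compared against
#' the tolerable weekly intake.
#'
#' The area-specific rice Cd geometric mean used for subjects with missing
#' rice Cd is computed from the cohort's own rice Cd values.
#'
#' @param subjects subject `data.frame` (see [read_subjects()]).
#' @param concentrations concentration record table.
#' @param mapping `dhq_mapping` rule list.
#' @param twi tolerable weekly intake (ug/kg BW/week).
#' @param mass_change_factors optional named factor vector (see
#'   [subject_daily_intake()]).
#' @param apply_filters apply [apply_exclusions()] first?
#' @param brown_rice_factor polished-rice equivalence factor.
#' @return an object of class `cd_exposure`: a list with `intake` (the
#'   per-subject results), `exclusions`, `unmapped`, `twi`, `n` and `call`.
#' @examples
#' cohort <- generate_cohort(cohort_params("area_B", n = 50), seed = 1)
#' fit <- cd_exposure(cohort)
#' fit
#' summary(fit)
#' @export
cd_exposure <- function(subjects, concentrations = cd_concentrations(),
                        mapping = default_mapping(), twi = 7,
                        mass_change_factors = NULL, apply_filters = TRUE,
                        brown_rice_factor = 0.9) {
  if (is.null(mass_change_factors))
    mass_change_factors <- attr(subjects, "mass_change_factors")
  excl <- if (apply_filters) apply_exclusions(subjects)
          else list(kept = subjects,
                    log = data.frame(id = character(0), reason = character(0)))
  kept <- excl$kept
  if (!nrow(kept)) stop("no subjects remain after exclusions")
  gm <- tapply(kept$rice_cd_mg_per_kg, kept$area,
               function(v) exp(mean(log(v[!is.na(v) & v > 0]))))
  res <- .cohort_intakes(kept, mapping, concentrations, cohort_rice_gm = gm,
                         mass_change_factors = mass_change_factors, twi = twi,
                         brown_rice_factor = brown_rice_factor)
  structure(list(intake = res$intake, exclusions = excl$log,
                 unmapped = res$unmapped, twi = twi,
                 rice_gm = gm, n = nrow(kept), call = match.call()),
            class = "cd_exposure")
}

#' @export
print.cd_exposure <- function(x, ...) {
  cat("Dietary Cd exposure assessment (individual food analysis)\n")
  cat(sprintf("  subjects: %d (%d excluded)\n", x$n, nrow(x$exclusions)))
  w <- x$intake$weekly_ug_kg_bw
  cat(sprintf("  total Cd intake, median: %.1f ug/day\n",
              stats::median(x$intake$total_ug_day)))
  cat(sprintf("  weekly intake per BW, median: %.1f ug/kg BW/week\n",
              stats::median(w)))
  cat(sprintf("  at or above TWI (%g): %d (%.1f%%)\n", x$twi,
              sum(w >= x$twi), 100 * mean(w >= x$twi)))
  invisible(x)
}

#' @describeIn cd_exposure cohort tables: per-subgroup daily intake
#'   summaries, the TWI exceedance partition and age-stratified weekly
#'   intake.
#' @param object,x a `cd_exposure` fit.
#' @param ... unused.
#' @export
summary.cd_exposure <- function(object, ...) {
  it <- object$intake
  subgroup_tab <- do.call(rbind, lapply(
    c(total = "total_ug_day", stats::setNames(REPORTING_SUBGROUPS,
                                              REPORTING_SUBGROUPS)),
    function(col) quartile_summary(it[[col]])))
  subgroup_tab <- cbind(quantity = rownames(subgroup_tab), subgroup_tab)
  rownames(subgroup_tab) <- NULL
  structure(list(
    subgroups = subgroup_tab,
    exceedance = classify_exceedance(it$weekly_ug_kg_bw, object$twi),
    by_age = cohort_summary(it$weekly_ug_kg_bw, it$age),
    twi = object$twi, n = object$n
  ), class = "summary.cd_exposure")
}

#' @export
print.summary.cd_exposure <- function(x, ...) {
  cat("Daily Cd intake by subgroup (ug/day):\n")
  tab <- x$subgroups
  tab[-1] <- lapply(tab[-1], function(v) round(v, 1))
  print(tab, row.names = FALSE)
  cat("\nWeekly intake per body weight vs TWI of", x$twi, "ug/kg BW/week:\n")
  print(x$exceedance, row.names = FALSE)
  cat("\nWeekly intake by age stratum (ug/kg BW/week):\n")
  tab <- x$by_age
  tab[-1] <- lapply(tab[-1], function(v) round(v, 1))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn cd_exposure histogram of weekly intake per body weight with
#'   the TWI marked.
#' @param main plot title.
#' @export
plot.cd_exposure <- function(x, main = "Weekly Cd intake per body weight",
                             ...) {
  w <- x$intake$weekly_ug_kg_bw
  graphics::hist(w, breaks = seq(0, ceiling(max(w)) + 1, by = 1),
                 xlab = "ug/kg BW/week", main = main, col = "grey85", ...)
  graphics::abline(v = x$twi, lty = 2, col = "red3")
  invisible(x)
}
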