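#' Read a questionnaire-to-concentration mapping config
#'
#' Loads the declarative rules that reconcile diet-history-questionnaire
#' (DHQ) items with the measured concentration table: a DHQ item may map
#' directly to one measured item, split across several with weights (e.g.
#' barley rice as 70% rice / 30% wheat flour), use the average concentration
#' of a list of items (e.g. tofu as the average of silken and cotton tofu),
#' use the subject's own rice Cd (`RICE_INDIVIDUAL`), or be excluded
#' (`excluded: true`) when its Cd content is below detection.
#'
#' @param path path to a YAML config; defaults to the packaged rule set.
#' @param table optional concentration record `data.frame`; when supplied,
#'   every referenced item is checked against it.
#' @return a named list of rules of class `dhq_mapping`. Each rule has
#'   `dhq_item`, `excluded`, `mass_change_factor` and `components` (a list
#'   of `source`/`average_of` + `weight` entries).
#' @export
read_mapping <- function(path, table = NULL) {
  if (!file.exists(path)) stop("mapping config not found: ", path)
  cfg <- yaml::read_yaml(path)
  rules <- lapply(names(cfg), function(key) {
    entry <- cfg[[key]]
    excluded <- isTRUE(entry$excluded)
    comps <- if (excluded) list() else entry$components
    if (!excluded && (is.null(comps) || !length(comps)))
      stop("mapping entry '", key, "' has no components and is not excluded")
    if (excluded && !is.null(entry$components))
      stop("mapping entry '", key, "' is excluded but lists components")
    mcf <- if (is.null(entry$mass_change_factor)) 1.0
           else as.numeric(entry$mass_change_factor)
    if (!is.finite(mcf) || mcf <= 0)
      stop("mapping entry '", key, "': mass_change_factor must be > 0")
    comps <- lapply(comps, function(cm) {
      w <- if (is.null(cm$weight)) 1.0 else as.numeric(cm$weight)
      if (!is.finite(w) || w < 0 || w > 1)
        stop("mapping entry '", key, "': weight outside [0, 1]")
      list(source = cm$source, average_of = unlist(cm$average_of), weight = w)
    })
    if (!excluded) {
      wsum <- sum(vapply(comps, `[[`, numeric(1), "weight"))
      if (abs(wsum - 1) > 1e-9)
        stop("mapping entry '", key, "': component weights sum to ",
             format(wsum), ", not 1")
    }
    structure(list(dhq_item = key, excluded = excluded,
                   components = comps, mass_change_factor = mcf),
              class = "mapping_rule")
  })
  names(rules) <- names(cfg)
  rules <- structure(rules, class = "dhq_mapping")
  if (!is.null(table)) validate_mapping(rules, table)
  rules
}

#' Packaged default mapping
#'
#' The default reconciliation rule set covering every questionnaire item
#' named by the study protocol, validated against the packaged
#' concentration table.
#'
#' @return a `dhq_mapping` rule list (see [read_mapping()]).
#' @export
default_mapping <- function() {
  read_mapping(system.file("extdata", "dhq_mapping.yaml",
                           package = "cdexposure"),
               table = cd_concentrations())
}

referenced_items <- function(rule) {
  unlist(lapply(rule$components, function(cm) {
    if (!is.null(cm$average_of)) cm$average_of else cm$source
  }))
}

validate_mapping <- function(rules, table) {
  known <- unique(table$item)
  for (rule in rules) {
    refs <- setdiff(referenced_items(rule), "RICE_INDIVIDUAL")
    dangling <- setdiff(refs, known)
    if (length(dangling))
      stop("mapping entry '", rule$dhq_item,
           "' references items absent from the concentration table: ",
           paste(dangling, collapse = ", "))
  }
  invisible(rules)
}

#' The default questionnaire catalog
#'
#' The questionnaire items known to the packaged mapping - the items named
#' by the study protocol. Items outside this catalog contribute zero intake
#' with a logged warning.
#'
#' @return character vector of DHQ item keys.
#' @export
dhq_catalog <- function() names(default_mapping())

#' Resolve the effective Cd concentration of one questionnaire item
#'
#' Applies a mapping rule against a concentration table: a weighted sum of
#' pooled arithmetic-mean concentrations (or averages of such means for
#' `average_of` components). `RICE_INDIVIDUAL` resolves to the subject's own
#' rice Cd (mg/kg), reduced to its polished-rice equivalent
#' (`brown_rice_factor`, default 0.9) when the subject eats brown rice, or
#' substituted by the cohort geometric mean when missing. Excluded rules
#' resolve to 0.
#'
#' @param rule a `mapping_rule` from the rule list.
#' @param table concentration record `data.frame`.
#' @param subject optional one-row subject `data.frame` (needed when the
#'   rule uses `RICE_INDIVIDUAL`), with `rice_cd_mg_per_kg` and `brown_rice`.
#' @param cohort_rice_gm fallback rice Cd geometric mean (mg/kg) for
#'   subjects with missing rice Cd.
#' @param rule_censored substitution rule for censored replicates entering
#'   pooled means (default `"zero"`: non-detected values contribute nothing).
#' @param brown_rice_factor multiplier converting brown-rice Cd to its
#'   polished-rice equivalent.
#' @return effective concentration in ug/g (= mg/kg).
#' @export
resolve_concentration <- function(rule, table, subject = NULL,
                                  cohort_rice_gm = NULL,
                                  rule_censored = "zero",
                                  brown_rice_factor = 0.9) {
  if (rule$excluded) return(0)
  total <- 0
  for (cm in rule$components) {
    conc <- if (!is.null(cm$average_of)) {
      mean(vapply(cm$average_of, function(it)
        pooled_mean(table, it, rule_censored), numeric(1)))
    } else if (identical(cm$source, "RICE_INDIVIDUAL")) {
      .rice_concentration(subject, cohort_rice_gm, brown_rice_factor)
    } else {
      pooled_mean(table, cm$source, rule_censored)
    }
    total <- total + cm$weight * conc
  }
  total
}

.rice_concentration <- function(subject, cohort_rice_gm, brown_rice_factor) {
  if (is.null(subject))
    stop("a subject is required to resolve RICE_INDIVIDUAL")
  cd <- subject$rice_cd_mg_per_kg
  if (is.na(cd)) {
    if (is.null(cohort_rice_gm) || is.na(cohort_rice_gm))
      stop("subject ", subject$id,
           " lacks rice Cd and no cohort geometric mean is available")
    cd <- cohort_rice_gm
  }
  if (isTRUE(as.logical(subject$brown_rice))) cd <- brown_rice_factor * cd
  cd
}

#' Audit mapping coverage
#'
#' Cross-checks a rule set against a questionnaire catalog and a
#' concentration table, reporting questionnaire items with no rule,
#' measured items never referenced by any rule (foods measured but absent
#' from the questionnaire), and explicit exclusions.
#'
#' @param rules a `dhq_mapping` rule list.
#' @param catalog character vector of questionnaire item keys.
#' @param table concentration record `data.frame`.
#' @return a list of class `mapping_report` with `unmapped_dhq_items`,
#'   `unused_concentration_items` and `excluded_items`.
#' @export
validate_coverage <- function(rules, catalog = dhq_catalog(),
                              table = cd_concentrations()) {
  used <- unique(unlist(lapply(rules, referenced_items)))
  used <- setdiff(used, "RICE_INDIVIDUAL")
  excluded <- names(rules)[vapply(rules, `[[`, logical(1), "excluded")]
  structure(list(
    unmapped_dhq_items = setdiff(catalog, names(rules)),
    unused_concentration_items = setdiff(unique(table$item), used),
    excluded_items = excluded
  ), class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("Mapping coverage report\n")
  cat("  unmapped questionnaire items: ", length(x$unmapped_dhq_items), "\n")
  cat("  unused measured items:        ", length(x$unused_concentration_items),
      "\n")
  cat("  excluded questionnaire items: ", length(x$excluded_items), "\n")
  invisible(x)
}
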