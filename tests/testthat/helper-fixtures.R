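# small in-code fixtures shared across test files

# a minimal concentration table: two areas for one item, censored rows, rice
tiny_conc_table <- function() {
  data.frame(
    item = c("itemX", "itemX", "Silken tofu", "Cotton tofu", "censoredY",
             "censoredY"),
    subgroup = c("vegetables", "vegetables", "soybeans", "soybeans",
                 "fish_shellfish", "fish_shellfish"),
    area = c("A", "B", "pooled", "pooled", "pooled", "pooled"),
    replicate = c(1, 1, 1, 1, 1, 2),
    value = c(0.01, 0.03, 0.015, 0.027, NA, NA),
    censored = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    lod = c(NA, NA, NA, NA, 0.005, 0.005),
    stringsAsFactors = FALSE)
}

# one-subject table: rice plus one mapped item
tiny_subjects <- function(rice_cd = 0.158, rice_g = 371.8, brown = FALSE,
                          energy = 2000, weight = 54.5, n = 1,
                          extra = list(miso = 0)) {
  df <- data.frame(id = sprintf("s%d", seq_len(n)), area = "A", age = 55,
                   height_cm = 152, weight_kg = weight, energy_kcal = energy,
                   rice_cd_mg_per_kg = rice_cd, brown_rice = brown,
                   rice = rice_g, stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# cached package fixtures (loading the YAML/CSVs once per test run)
pkg_conc <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- cd_concentrations()
    tab
  }
})
pkg_map <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_mapping()
    m
  }
})
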