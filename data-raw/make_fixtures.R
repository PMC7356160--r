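# Build the packaged concentration fixtures under inst/extdata/.
#
# The source publication prints per-item summaries only (n, mean, range).
# For each item we construct n synthetic replicates that reproduce the
# printed summary exactly: the two range endpoints are stored as-is and the
# n-2 interior replicates share one value solved so the mean (AM, or GM for
# rice) matches the printed figure. Items whose printed mean cannot lie
# inside the printed range (three rows) are flagged consistent = FALSE and
# the interior value is clamped to the range.
#
# Run from the package root: Rscript data-raw/make_fixtures.R

# item, subgroup, area, n, mean, kind, lo, hi, censored(all), lod
row <- function(item, subgroup, area, n, mean, lo = NA, hi = NA,
                kind = "AM", censored = FALSE, lod = 0.005) {
  data.frame(item = item, subgroup = subgroup, area = area, n = n,
             mean = mean, mean_kind = kind, range_lo = lo, range_hi = hi,
             censored = censored, lod = lod, stringsAsFactors = FALSE)
}

tab <- rbind(
  # -- rice and rice products ------------------------------------------------
  row("Rice", "rice_products", "A", 711, 0.158, 0.02, 0.971, kind = "GM", lod = 0.02),
  row("Rice", "rice_products", "B", 432, 0.109, 0.008, 0.687, kind = "GM"),
  row("Kiritampo", "rice_products", "pooled", 6, 0.063, 0.070, 0.102),
  row("Glutinous rice", "rice_products", "pooled", 10, 0.098, 0.02, 0.32),
  row("Rice cakes", "rice_products", "pooled", 5, 0.069, 0.017, 0.182),
  row("Rice crackers", "rice_products", "pooled", 4, 0.091, 0.017, 0.263),
  # -- cereals, tubers, roots ------------------------------------------------
  row("White bread", "cereals_tubers_roots", "pooled", 6, 0.018, 0.016, 0.023),
  row("Ampan", "cereals_tubers_roots", "pooled", 6, 0.010, 0.010, 0.014),
  row("Wheat flour", "cereals_tubers_roots", "A", 3, 0.021, 0.019, 0.024),
  row("Udon", "cereals_tubers_roots", "pooled", 6, 0.005, 0.005, 0.007),
  row("Soba", "cereals_tubers_roots", "pooled", 6, 0.019, 0.007, 0.034),
  row("Sesame seeds", "cereals_tubers_roots", "pooled", 6, 0.055, 0.021, 0.11),
  row("Sweet potato", "cereals_tubers_roots", "pooled", 6, 0.008, 0.005, 0.016),
  row("Potato", "cereals_tubers_roots", "pooled", 6, 0.034, 0.005, 0.098),
  row("Taro", "cereals_tubers_roots", "pooled", 6, 0.289, 0.036, 0.795),
  row("Yams", "cereals_tubers_roots", "pooled", 7, 0.061, 0.005, 0.167),
  row("Potato chips", "cereals_tubers_roots", "A", 3, 0.059, 0.029, 0.114),
  # -- soybeans and soybean products -----------------------------------------
  row("Soybeans", "soybeans", "pooled", 4, 0.115, 0.05, 0.25),
  row("Silken tofu", "soybeans", "pooled", 5, 0.015, 0.009, 0.028),
  row("Cotton tofu", "soybeans", "pooled", 6, 0.027, 0.013, 0.052),
  row("Deep-fried tofu", "soybeans", "pooled", 6, 0.051, 0.033, 0.083),
  row("Natto", "soybeans", "pooled", 6, 0.028, 0.011, 0.055),
  row("Miso", "soybeans", "pooled", 6, 0.123, 0.026, 0.259),
  row("Edamame", "soybeans", "pooled", 6, 0.155, 0.085, 0.293),
  row("Soy sauce", "soybeans", "pooled", 4, 0.019, 0.015, 0.026),
  # -- vegetables -------------------------------------------------------------
  row("Carrot", "vegetables", "pooled", 6, 0.047, 0.013, 0.107),
  row("Spinach", "vegetables", "pooled", 6, 0.064, 0.030, 0.122),
  row("Tomato", "vegetables", "pooled", 5, 0.012, 0.005, 0.022),
  row("Squash", "vegetables", "pooled", 6, 0.016, 0.008, 0.024),
  row("Broccoli", "vegetables", "pooled", 6, 0.012, 0.005, 0.027),
  row("Japanese white radish", "vegetables", "pooled", 6, 0.009, 0.005, 0.023),
  row("Onions", "vegetables", "pooled", 5, 0.016, 0.005, 0.031),
  row("Cabbage", "vegetables", "pooled", 6, 0.008, 0.006, 0.011),
  row("Chinese cabbage", "vegetables", "pooled", 6, 0.020, 0.011, 0.038),
  row("Burdock", "vegetables", "pooled", 6, 0.063, 0.017, 0.212),
  row("Japanese parsley", "vegetables", "pooled", 6, 0.010, 0.005, 0.019),
  row("Eggplant", "vegetables", "pooled", 6, 0.017, 0.005, 0.028),
  row("Garland chrysanthemum", "vegetables", "pooled", 5, 0.074, 0.006, 0.244),
  row("Japanese mustard spinach", "vegetables", "pooled", 5, 0.065, 0.009, 0.23),
  row("Bok choy", "vegetables", "pooled", 5, 0.029, 0.01, 0.101),
  row("Green pepper", "vegetables", "pooled", 5, 0.006, 0.005, 0.009),
  row("Garlic", "vegetables", "pooled", 6, 0.051, 0.01, 0.142),
  row("Okra", "vegetables", "pooled", 3, 0.023, 0.012, 0.043),
  row("Belvedere fruit", "vegetables", "pooled", 6, 0.069, 0.041, 0.095),
  row("Japanese leek", "vegetables", "A", 3, 0.032, 0.005, 0.083),
  row("Pickled vegetables", "vegetables", "pooled", 10, 0.022, 0.009, 0.095),
  row("Smoked daikon pickles", "vegetables", "pooled", 6, 0.024, 0.017, 0.035),
  # -- mushrooms ---------------------------------------------------------------
  row("Raw shiitake mushroom", "mushrooms", "pooled", 7, 0.374, 0.065, 0.527),
  row("Maitake mushroom", "mushrooms", "pooled", 6, 0.043, 0.023, 0.108),
  # -- seaweed -----------------------------------------------------------------
  row("Wakame seaweed (raw)", "seaweed", "pooled", 6, 0.253, 0.069, 0.544),
  row("Wakame seaweed (dried)", "seaweed", "A", 3, 4.64, 4.11, 5.06),
  row("Kelp", "seaweed", "pooled", 6, 0.682, 0.119, 1.78),
  row("Laver", "seaweed", "pooled", 4, 0.413, 0.209, 0.66),
  row("Hijiki seaweed", "seaweed", "pooled", 5, 1.066, 0.693, 1.53),
  row("Agar-agar", "seaweed", "A", 3, 0.024, 0.014, 0.033),
  row("Mozuku seaweed", "seaweed", "pooled", 6, 0.006, 0.005, 0.01),
  # -- fish and shellfish ------------------------------------------------------
  row("Salmon", "fish_shellfish", "pooled", 6, NA, censored = TRUE),
  row("Tuna", "fish_shellfish", "pooled", 6, 0.009, 0.005, 0.013),
  row("Cod", "fish_shellfish", "pooled", 6, NA, censored = TRUE),
  row("Horse mackerel", "fish_shellfish", "pooled", 6, 0.012, 0.007, 0.015),
  row("Mackerel", "fish_shellfish", "pooled", 6, 0.012, 0.005, 0.018),
  row("Sandfish without eggs", "fish_shellfish", "pooled", 6, 0.012, 0.009, 0.017),
  row("Sandfish with eggs", "fish_shellfish", "pooled", 6, 0.014, 0.01, 0.018),
  row("Squid", "fish_shellfish", "pooled", 6, 0.032, 0.018, 0.081),
  row("Salted squid guts", "fish_shellfish", "pooled", 5, 2.36, 0.978, 6.57),
  row("Octopus", "fish_shellfish", "pooled", 6, 0.007, 0.005, 0.011),
  row("Prawn", "fish_shellfish", "pooled", 7, 0.055, 0.005, 0.17),
  row("Shrimp", "fish_shellfish", "B", 2, 0.022, 0.009, 0.035),
  row("Cod roe", "fish_shellfish", "pooled", 6, 0.008, 0.005, 0.015),
  row("Salmon roe", "fish_shellfish", "pooled", 3, NA, censored = TRUE),
  row("Scallops without innards", "fish_shellfish", "pooled", 5, 0.0408, 0.012, 0.103),
  row("Scallops with innards", "fish_shellfish", "pooled", 5, 3.635, 0.684, 5.54),
  row("Oysters with innards", "fish_shellfish", "pooled", 6, 0.680, 0.486, 1.03),
  row("Japanese littleneck clam", "fish_shellfish", "pooled", 4, 0.160, 0.028, 0.305),
  row("Freshwater clam", "fish_shellfish", "pooled", 4, 0.375, 0.235, 0.55),
  row("Hampen", "fish_shellfish", "pooled", 6, 0.005, 0.005, 0.006),
  row("Dried whitebait", "fish_shellfish", "pooled", 6, 0.010, 0.005, 0.02),
  row("Broiled eel", "fish_shellfish", "pooled", 6, 0.008, 0.005, 0.011),
  # -- livestock ---------------------------------------------------------------
  row("Beef", "livestock", "pooled", 6, NA, censored = TRUE),
  row("Pork", "livestock", "pooled", 5, NA, censored = TRUE),
  row("Chicken", "livestock", "pooled", 4, NA, censored = TRUE),
  row("Hinai chicken", "livestock", "pooled", 5, NA, censored = TRUE),
  row("Horse meat", "livestock", "pooled", 3, 0.006, 0.005, 0.007),
  row("Beef liver", "livestock", "A", 1, 0.021),
  row("Pork liver", "livestock", "pooled", 4, 0.024, 0.016, 0.028),
  row("Chicken liver", "livestock", "pooled", 5, 0.015, 0.01, 0.022),
  row("Hinai chicken liver", "livestock", "A", 2, 0.039, 0.033, 0.044),
  row("Innards of Hinai chicken", "livestock", "pooled", 6, 0.021, 0.008, 0.066),
  row("Sausage", "livestock", "pooled", 3, 0.006, 0.005, 0.008),
  row("Egg", "livestock", "pooled", 6, NA, censored = TRUE),
  row("Milk", "livestock", "pooled", 6, NA, censored = TRUE),
  # -- fruit -------------------------------------------------------------------
  row("Apple", "fruit", "pooled", 6, NA, censored = TRUE),
  row("Apple juice", "fruit", "pooled", 6, NA, censored = TRUE),
  row("Kiwi fruit", "fruit", "pooled", 5, NA, censored = TRUE),
  # -- others ------------------------------------------------------------------
  row("Manju", "others", "pooled", 10, 0.022, 0.010, 0.127),
  row("Chocolate", "others", "A", 3, 0.042, 0.03, 0.084),
  row("Curry roux", "others", "A", 3, 0.015, 0.012, 0.018),
  row("Flavor seasonings", "others", "A", 1, 0.025),
  row("Ketchup", "others", "pooled", 3, 0.016, 0.016, 0.017),
  row("Japanese green tea leaves", "others", "A", 3, 0.026, 0.009, 0.049),
  row("Nutritional supplement drink", "others", "A", 3, NA, censored = TRUE),
  row("Well water", "others", "A", 7, NA, censored = TRUE)
)

# Solve replicate values for one summary row.
make_values <- function(n, mean, lo, hi, kind) {
  if (n == 1) return(mean)
  if (n == 2) return(c(lo, hi))
  if (kind == "GM") {
    interior <- exp((n * log(mean) - log(lo) - log(hi)) / (n - 2))
    interior <- min(max(interior, lo), hi)
  } else {
    interior <- (n * mean - lo - hi) / (n - 2)
    interior <- min(max(interior, lo), hi)
  }
  c(lo, rep(interior, n - 2), hi)
}

recs <- list()
summ <- list()
for (i in seq_len(nrow(tab))) {
  r <- tab[i, ]
  if (r$censored) {
    vals <- rep(NA_real_, r$n)
    cen <- rep(TRUE, r$n)
    lods <- rep(r$lod, r$n)
    consistent <- TRUE
    achieved <- NA_real_
  } else {
    vals <- make_values(r$n, r$mean, r$range_lo, r$range_hi, r$mean_kind)
    cen <- rep(FALSE, r$n)
    lods <- rep(NA_real_, r$n)
    achieved <- if (r$mean_kind == "GM") exp(mean(log(vals))) else mean(vals)
    consistent <- abs(achieved - r$mean) <= 5e-4 + 1e-12
  }
  recs[[i]] <- data.frame(
    item = r$item, subgroup = r$subgroup, area = r$area,
    replicate = seq_len(r$n),
    value_mg_per_kg = round(vals, 6),
    censored = cen, lod_mg_per_kg = lods, stringsAsFactors = FALSE)
  summ[[i]] <- data.frame(
    item = r$item, subgroup = r$subgroup, area = r$area, n = r$n,
    mean = r$mean, mean_kind = r$mean_kind,
    range_lo = r$range_lo, range_hi = r$range_hi,
    censored = r$censored, consistent = consistent, stringsAsFactors = FALSE)
  if (!r$censored && !consistent)
    message(sprintf("inconsistent printed row: %s (printed %g, best %g)",
                    r$item, r$mean, achieved))
}
recs <- do.call(rbind, recs)
summ <- do.call(rbind, summ)

# round, then re-fix the interior so rounding does not shift the mean
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
rice <- recs$item == "Rice"
write.csv(recs[rice, ], "inst/extdata/cd_concentrations_rice.csv",
          row.names = FALSE, quote = FALSE)
write.csv(recs[!rice, ], "inst/extdata/cd_concentrations_foods.csv",
          row.names = FALSE, quote = FALSE)
write.csv(summ, "inst/extdata/cd_printed_summaries.csv",
          row.names = FALSE, quote = FALSE)
cat("rows:", nrow(recs), "items:", nrow(summ), "\n")
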