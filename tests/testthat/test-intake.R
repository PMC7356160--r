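test_that("exclusion filters implement the stated boundaries and are idempotent", {
  s <- tiny_subjects(n = 5)
  s$energy_kcal <- c(2000, 1000, 3500, 900, 2500)
  s$rice <- c(300, 300, 300, 300, 0)
  res <- apply_exclusions(s)
  expect_equal(res$kept$id, "s1")
  expect_setequal(res$log$reason,
                  c("energy_low", "energy_high", "zero_rice"))
  # boundary values are excluded (<=1000, >=3500)
  expect_true("s2" %in% res$log$id)
  expect_true("s3" %in% res$log$id)
  again <- apply_exclusions(res$kept)
  expect_identical(again$kept, res$kept)
  expect_equal(nrow(again$log), 0)
})

test_that("per-subject intake multiplies intake by concentration", {
  m <- pkg_map(); tab <- pkg_conc()
  s <- tiny_subjects(rice_cd = 0.158, rice_g = 371.8)
  r <- subject_daily_intake(s, m, tab)
  expect_equal(r$rice_and_rice_products, 371.8 * 0.158, tolerance = 1e-10)
  expect_equal(r$total_ug_day, r$rice_and_rice_products)

  # brown rice: concentration reduced to its polished equivalent
  s2 <- tiny_subjects(rice_cd = 0.2, rice_g = 100, brown = TRUE)
  r2 <- subject_daily_intake(s2, m, tab)
  expect_equal(r2$rice_and_rice_products, 0.9 * 0.2 * 100)

  # empty diet
  s3 <- tiny_subjects(rice_g = 0, extra = list(miso = 0))
  r3 <- subject_daily_intake(s3, m, tab)
  expect_equal(r3$total_ug_day, 0)
  expect_true(all(r3[, c("rice_and_rice_products", "soybeans")] == 0))

  # mass-change factors multiply the contribution
  r4 <- subject_daily_intake(s, m, tab, mass_change_factors = c(rice = 0.5))
  expect_equal(r4$rice_and_rice_products, 0.5 * 371.8 * 0.158)
})

test_that("subgroup accumulation routes composite items correctly", {
  m <- pkg_map(); tab <- pkg_conc()
  s <- tiny_subjects(rice_cd = 0.1, rice_g = 0,
                     extra = list(boiled_barley_rice = 100, miso = 50,
                                  oysters = 10))
  r <- subject_daily_intake(s, m, tab)
  wheat <- pooled_mean(tab, "Wheat flour")
  expect_equal(r$rice_and_rice_products, 0.7 * 0.1 * 100)
  expect_equal(r$cereals_tubers_roots, 0.3 * wheat * 100)
  expect_equal(r$soybeans, 50 * pooled_mean(tab, "Miso"))
  expect_equal(r$seafood, 10 * pooled_mean(tab, "Oysters with innards"))
  expect_equal(r$total_ug_day,
               sum(r[, c("rice_and_rice_products", "cereals_tubers_roots",
                         "soybeans", "vegetables", "mushrooms", "seafood",
                         "others")]))
})

test_that("intake is additive: doubling the diet doubles every subgroup", {
  co <- generate_cohort(cohort_params("area_B", n = 40), seed = 7)
  doubled <- co
  items <- setdiff(names(co), c("id", "area", "age", "height_cm", "weight_kg",
                                "energy_kcal", "rice_cd_mg_per_kg",
                                "brown_rice"))
  doubled[items] <- doubled[items] * 2
  attr(doubled, "mass_change_factors") <- attr(co, "mass_change_factors")
  f1 <- suppressWarnings(cd_exposure(co, apply_filters = FALSE))
  f2 <- suppressWarnings(cd_exposure(doubled, apply_filters = FALSE))
  for (col in c("rice_and_rice_products", "soybeans", "seafood",
                "total_ug_day", "weekly_ug_kg_bw"))
    expect_equal(f2$intake[[col]], 2 * f1$intake[[col]], tolerance = 1e-12)
})

test_that("weekly conversion and exceedance classification match definitions", {
  expect_equal(weekly_per_bw(55.7, 54.5), 7 * 55.7 / 54.5)
  expect_equal(weekly_per_bw(0, 60), 0)
  expect_equal(weekly_per_bw(54.5, 54.5), 7)
  expect_error(weekly_per_bw(10, 0), "positive")

  cls <- classify_exceedance(c(6.9, 7.0, 7.1))
  expect_equal(cls$n, c(1, 2))          # the boundary value exceeds
  expect_equal(sum(cls$n), 3)
  expect_equal(cls$pct, c(33.3, 66.7))

  # exceedance percentage equals the complementary empirical CDF
  set.seed(11)
  w <- rlnorm(500, log(6), 0.5)
  cls2 <- classify_exceedance(w, 7)
  expect_equal(cls2$n[2] / 500, 1 - ecdf(w)(7 - 1e-12), tolerance = 1e-9)
})

test_that("cohort summaries report quartiles and age strata", {
  cs <- cohort_summary(rep(5, 10))
  expect_equal(cs$median[1], 5); expect_equal(cs$q25[1], 5)
  cs2 <- cohort_summary(1:5)
  expect_equal(cs2$median[1], 3)
  expect_equal(cs2$min[1], 1); expect_equal(cs2$max[1], 5)
  cs3 <- cohort_summary(c(1, 2, 3), age = c(25, 25, 45))
  expect_equal(cs3$n[cs3$stratum == "20-29"], 2)
  expect_equal(cs3$n[cs3$stratum == "30-39"], 0)
  expect_true(is.na(cs3$median[cs3$stratum == "30-39"]))
  expect_true(all(cs3$q25 <= cs3$median, na.rm = TRUE))
})

test_that("the exposure fit substitutes missing rice Cd with the area GM", {
  co <- generate_cohort(cohort_params("area_A", n = 30), seed = 3)
  expect_true(is.na(co$rice_cd_mg_per_kg[1]))   # one missing sample
  fit <- suppressWarnings(cd_exposure(co))
  gm <- exp(mean(log(co$rice_cd_mg_per_kg[-1])))
  expect_equal(unname(fit$rice_gm["A"]), gm)
  mcf <- attr(co, "mass_change_factors")[["rice"]]
  expect_equal(fit$intake$rice_and_rice_products[1],
               gm * co$rice[1] * mcf, tolerance = 1e-9)
})

test_that("subject tables round-trip through CSV", {
  co <- generate_cohort(cohort_params("area_B", n = 15), seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_subjects(co, tmp)
  back <- read_subjects(tmp)
  expect_equal(back$weight_kg, co$weight_kg)
  expect_equal(back$rice_cd_mg_per_kg, co$rice_cd_mg_per_kg,
               tolerance = 1e-12)
  expect_equal(back$miso, co$miso, tolerance = 1e-12)
  expect_identical(back$brown_rice, co$brown_rice)
})
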