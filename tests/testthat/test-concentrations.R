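test_that("the packaged table loads with validated records", {
  tab <- pkg_conc()
  expect_true(all(tab$subgroup %in% c("rice_products", "cereals_tubers_roots",
                                      "soybeans", "vegetables", "mushrooms",
                                      "seaweed", "fish_shellfish", "livestock",
                                      "fruit", "others")))
  expect_true(all(tab$value[!tab$censored] >= 0))
  expect_true(all(is.na(tab$value[tab$censored])))
  expect_true(all(tab$lod[tab$censored] > 0))
  # shiitake replicates reproduce the printed mean
  sh <- tab[tab$item == "Raw shiitake mushroom", ]
  expect_equal(nrow(sh), 7)
  expect_equal(summarize_item(sh)$mean, 0.374, tolerance = 1e-6)
})

test_that("malformed tables are rejected with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  bad <- data.frame(item = "x", subgroup = "vegetables", area = "A",
                    replicate = 1, value_mg_per_kg = -0.1, censored = FALSE,
                    lod_mg_per_kg = NA)
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_concentration_table(tmp), "negative")

  bad$value_mg_per_kg <- 0.1
  bad$subgroup <- "not_a_subgroup"
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_concentration_table(tmp), "subgroup")

  dup <- rbind(bad, bad)
  dup$subgroup <- "vegetables"
  write.csv(dup, tmp, row.names = FALSE)
  expect_error(read_concentration_table(tmp), "duplicate")
})

test_that("censored substitution follows the selected rule", {
  cen <- data.frame(item = "y", subgroup = "fish_shellfish", area = "pooled",
                    replicate = 1, value = NA, censored = TRUE, lod = 0.005)
  expect_equal(substitute_censored(cen, "half_lod"), 0.0025)
  expect_equal(substitute_censored(cen, "zero"), 0)
  expect_equal(substitute_censored(cen, "lod"), 0.005)
  ok <- cen; ok$value <- 0.374; ok$censored <- FALSE; ok$lod <- NA
  for (rule in c("zero", "half_lod", "lod"))
    expect_equal(substitute_censored(ok, rule), 0.374)
})

test_that("AM and GM summaries behave as their definitions require", {
  rec <- function(v) data.frame(item = "z", subgroup = "vegetables",
                                area = "pooled", replicate = seq_along(v),
                                value = v, censored = FALSE, lod = NA)
  expect_equal(summarize_item(rec(c(0.02, 0.02, 0.02)), "AM")$mean, 0.02)
  expect_equal(summarize_item(rec(c(0.1, 0.2, 0.4)), "GM")$mean, 0.2)
  expect_error(summarize_item(rec(c(0, 0.1)), "GM"), "nonzero substitution")
  # permutation invariance
  v <- c(0.065, 0.108, 0.527, 0.45, 0.38, 0.48, 0.608)
  expect_equal(summarize_item(rec(v), "AM")$mean, 0.374)
  for (seed in 1:3) {
    set.seed(seed)
    expect_identical(summarize_item(rec(sample(v)), "AM")$mean,
                     summarize_item(rec(v), "AM")$mean)
  }
})

test_that("pooled means combine areas and respect area-restricted items", {
  tab <- tiny_conc_table()
  expect_equal(pooled_mean(tab, "itemX"), 0.02)
  expect_error(pooled_mean(tab, "absent"), "not found")
  # chocolate was sampled in one area only
  choc <- pkg_conc()[pkg_conc()$item == "Chocolate", ]
  expect_true(all(choc$area == "A"))
  expect_equal(pooled_mean(pkg_conc(), "Chocolate"), mean(choc$value))
})

test_that("GM never exceeds AM on any fixture item", {
  tab <- pkg_conc()
  for (it in unique(tab$item[!tab$censored])) {
    rec <- tab[tab$item == it & !tab$censored, ]
    am <- summarize_item(rec, "AM")$mean
    gm <- summarize_item(rec, "GM")$mean
    expect_lte(gm, am + 1e-12)
  }
})

test_that("fixture replicates reproduce the printed summaries", {
  tab <- pkg_conc()
  printed <- cd_printed_summaries()
  inconsistent <- printed$item[!printed$consistent]
  # the three rows whose printed mean cannot lie inside the printed range
  expect_setequal(inconsistent, c("Kiritampo", "Ampan", "Chocolate"))
  for (i in which(!printed$censored)) {
    p <- printed[i, ]
    rec <- tab[tab$item == p$item & tab$area == p$area, ]
    expect_equal(nrow(rec), p$n)
    sm <- summarize_item(rec, p$mean_kind, rule = "half_lod")
    if (p$consistent) expect_lt(abs(sm$mean - p$mean), 5.1e-4)
    if (!is.na(p$range_lo)) {
      expect_gte(sm$range_lo, p$range_lo - 1e-9)
      expect_lte(sm$range_hi, p$range_hi + 1e-9)
    }
  }
})
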