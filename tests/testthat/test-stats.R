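test_that("2x2 chi-square matches hand computation and the base-R oracle", {
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  expect_equal(chi_square_2x2(rbind(c(5, 0), c(0, 5)))$statistic, 10)
  tab <- rbind(c(344, 368), c(268, 164))
  res <- chi_square_2x2(tab)
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  yates <- chi_square_2x2(tab, correct = TRUE)
  oracle_y <- suppressWarnings(chisq.test(tab, correct = TRUE))
  expect_equal(yates$statistic, unname(oracle_y$statistic), tolerance = 1e-10)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("the median test dichotomises at the grand median", {
  x <- c(1, 2, 3, 4, 5)
  res <- median_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # full separation: table {{0,3},{3,0}} and chi-square 6
  res2 <- median_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(res2$table), rbind(c(0, 3), c(3, 0)))
  expect_equal(res2$statistic, 6)
  # identical constant samples degenerate with a warning
  expect_warning(res3 <- median_test(c(2, 2), c(2, 2)), "degenerate")
  expect_equal(res3$p_value, 1)
  # statistic agrees with chi_square_2x2 on the dichotomised table
  set.seed(4)
  a <- rnorm(31); b <- rnorm(24, 0.5)
  res4 <- median_test(a, b)
  expect_equal(res4$statistic, chi_square_2x2(res4$table)$statistic)
})

test_that("the pooled t-test matches hand computation and t.test", {
  res <- t_test_unpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1 / sqrt(2/3), tolerance = 1e-12)
  oracle <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(t_test_unpaired(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(t_test_unpaired(c(2, 2), c(2, 2))$p_value, 1)
})

test_that("Grubbs screening removes documented extremes and no more", {
  g <- grubbs_iterative(c(1, 2, 3, 4, 100))
  expect_equal(g$outliers, 5L)
  expect_gt(g$G[1], g$critical[1])
  expect_equal(grubbs_iterative(c(1, 2, 3, 4, 5))$outliers, integer(0))
  expect_error(grubbs_iterative(c(1, 2)), "n >= 3")
  expect_equal(grubbs_iterative(rep(3, 10))$outliers, integer(0))
  # idempotence: cleaning a cleaned sample removes nothing
  set.seed(9)
  x <- c(rnorm(100), 15)
  g1 <- grubbs_iterative(x)
  expect_true(101 %in% g1$outliers)
  clean <- x[-g1$outliers]
  expect_length(grubbs_iterative(clean)$outliers, 0)
  # max_removals caps the iteration
  g2 <- grubbs_iterative(c(rnorm(50), 40, 80), max_removals = 1)
  expect_length(g2$outliers, 1)
})

test_that("Steel-Dwass reduces to the normal-approximation Wilcoxon at k = 2", {
  set.seed(21)
  x <- rnorm(15); y <- rnorm(18, 0.8)
  sd2 <- steel_dwass(c(x, y), rep(c("a", "b"), c(15, 18)))
  oracle <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(sd2$p_value, oracle$p.value, tolerance = 1e-10)
  # antisymmetry under swapping the pair
  swapped <- steel_dwass(c(y, x), rep(c("a", "b"), c(18, 15)))
  expect_equal(swapped$z, -sd2$z, tolerance = 1e-12)
})

test_that("Steel-Dwass flags no pairs under the null and monotone shifts above it", {
  g <- rep(c("a", "b", "c"), each = 12)
  res0 <- steel_dwass(rep(1:12, 3), g)
  expect_false(any(res0$significant))
  # six age-like strata with a monotone location shift: the youngest
  # stratum separates from the older, larger strata
  set.seed(31)
  ns <- c(27, 27, 109, 213, 278, 58)
  shift <- c(0, 0.25, 0.55, 0.7, 0.85, 0.8)
  vals <- unlist(mapply(function(n, mu) rlnorm(n, log(4) + mu, 0.45),
                        ns, shift))
  grp <- factor(rep(paste0("g", 1:6), ns), levels = paste0("g", 1:6))
  res <- steel_dwass(vals, grp)
  young_old <- res[res$group1 == "g1" & res$group2 %in% c("g4", "g5", "g6"), ]
  expect_true(all(young_old$significant))
})

test_that("both two-sample tests hold their nominal size under the null", {
  set.seed(42)
  nrep <- 10000; n <- 60
  x <- matrix(rnorm(nrep * n), n)
  y <- matrix(rnorm(nrep * n), n)
  tp <- vapply(seq_len(nrep),
               function(i) t_test_unpaired(x[, i], y[, i])$p_value,
               numeric(1))
  expect_lt(abs(mean(tp < 0.05) - 0.05), 0.01)
  mp <- vapply(seq_len(nrep),
               function(i) median_test(x[, i], y[, i])$p_value,
               numeric(1))
  # the median-dichotomy is slightly conservative at moderate n
  expect_lt(abs(mean(mp < 0.05) - 0.05), 0.015)
  expect_true(all(tp >= 0 & tp <= 1) && all(mp >= 0 & mp <= 1))
})
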