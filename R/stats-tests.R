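new_cd_test <- function(statistic, df, p_value, method, ...) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, ...), class = "cd_test")
}

#' @export
print.cd_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g", x$statistic))
  if (!is.null(x$df) && !is.na(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' `sum((O - E)^2 / E)` with 1 degree of freedom and an upper-tail p-value.
#' No continuity correction by default.
#'
#' @param table 2x2 matrix of counts.
#' @param correct apply the Yates continuity correction?
#' @return a `cd_test` with `statistic`, `df`, `p_value` and `expected`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("a 2x2 table is required")
  if (any(table < 0)) stop("negative counts")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal total: expected counts undefined")
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  new_cd_test(stat, 1, stats::pchisq(stat, 1, lower.tail = FALSE),
              if (correct) "Pearson chi-square (Yates-corrected)"
              else "Pearson chi-square", expected = expected)
}

#' Two-sample median test
#'
#' Mood's median test: the pooled grand median dichotomises both samples
#' (values equal to the grand median count as "at or below") and the
#' resulting 2x2 table is tested with the Pearson chi-square statistic
#' (1 df, no continuity correction by default).
#'
#' @param x,y numeric samples.
#' @param correct continuity correction flag passed to [chi_square_2x2()].
#' @return a `cd_test`; also carries `grand_median` and the 2x2 `table`
#'   (rows = groups, columns = above / at-or-below).
#' @export
median_test <- function(x, y, correct = FALSE) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  gm <- stats::median(c(x, y))
  tab <- rbind(x = c(sum(x > gm), sum(x <= gm)),
               y = c(sum(y > gm), sum(y <= gm)))
  colnames(tab) <- c("above", "at_or_below")
  if (any(colSums(tab) == 0)) {
    warning("degenerate dichotomy (all pooled values on one side); p = 1")
    return(new_cd_test(0, 1, 1, "Median test", grand_median = gm, table = tab))
  }
  ct <- chi_square_2x2(tab, correct = correct)
  new_cd_test(ct$statistic, 1, ct$p_value, "Median test",
              grand_median = gm, table = tab)
}

#' Unpaired Student's t-test (pooled variance)
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return a `cd_test` with the two-sided p-value.
#' @export
t_test_unpaired <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs n >= 2")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
    return(new_cd_test(if (p == 1) 0 else Inf, df, p,
                       "Unpaired Student's t-test"))
  }
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  new_cd_test(tval, df, 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
              "Unpaired Student's t-test")
}

#' Iterative Smirnov-Grubbs outlier screening
#'
#' Two-sided Grubbs test applied iteratively: at each step
#' `G = max |x_i - mean| / sd` is compared with the critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))`, `t` the upper `alpha/(2n)`
#' quantile of the t distribution with `n - 2` df; the most extreme point
#' is removed while `G` exceeds the critical value.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level per iteration.
#' @param max_removals cap on the number of removals.
#' @return an object of class `grubbs`: `outliers` (indices into the input,
#'   in removal order), `G`, `critical` (per iteration), `alpha`, `n_start`.
#' @export
grubbs_iterative <- function(values, alpha = 0.05, max_removals = Inf) {
  if (length(values) < 3) stop("Grubbs test needs n >= 3")
  idx <- seq_along(values)
  removed <- integer(0); Gs <- numeric(0); crits <- numeric(0)
  x <- values
  while (length(x) >= 3 && length(removed) < max_removals) {
    n <- length(x)
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    tq <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G <= crit) break
    drop <- which.max(dev)
    removed <- c(removed, idx[drop])
    Gs <- c(Gs, G); crits <- c(crits, crit)
    x <- x[-drop]; idx <- idx[-drop]
  }
  structure(list(outliers = removed, G = Gs, critical = crits,
                 alpha = alpha, n_start = length(values)),
            class = "grubbs")
}

#' @export
print.grubbs <- function(x, ...) {
  cat(sprintf("Iterative Smirnov-Grubbs screen (alpha = %g, n = %d)\n",
              x$alpha, x$n_start))
  if (!length(x$outliers)) cat("  no outliers\n")
  else cat("  removed indices:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For each pair of groups a Wilcoxon rank sum is computed on the two
#' groups alone, standardised with mean `n_i (n_i + n_j + 1) / 2` and the
#' tie-corrected variance, and referred to the studentized-range
#' distribution: the pair is significant at level `alpha` when
#' `sqrt(2) * |z|` exceeds the upper-`alpha` studentized-range quantile for
#' `k` groups and infinite df. For `k = 2` this reduces to the two-sided
#' normal-approximation Wilcoxon test.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (factor or coercible).
#' @param alpha family-wise significance level.
#' @return `data.frame` of class `steel_dwass`, one row per pair:
#'   `group1`, `group2`, `n1`, `n2`, `z`, `q` (= sqrt(2) |z|), `p_value`,
#'   `significant`.
#' @export
steel_dwass <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("at least two groups required")
  lev <- levels(groups)
  qcrit <- stats::qtukey(alpha, k, Inf, lower.tail = FALSE)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- values[groups == lev[i]]; xj <- values[groups == lev[j]]
    ni <- length(xi); nj <- length(xj)
    if (ni < 2 || nj < 2) {
      warning("pair ", lev[i], "-", lev[j], " skipped (group with n < 2)")
      next
    }
    N <- ni + nj
    r <- rank(c(xi, xj))
    W <- sum(r[seq_len(ni)])
    EW <- ni * (N + 1) / 2
    # tie correction on the pooled pair ranks
    ties <- table(c(xi, xj))
    tie_fac <- 1 - sum(ties^3 - ties) / (N^3 - N)
    VW <- ni * nj * (N + 1) / 12 * tie_fac
    if (VW == 0) { z <- 0 } else z <- (W - EW) / sqrt(VW)
    q <- sqrt(2) * abs(z)
    p <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      group1 = lev[i], group2 = lev[j], n1 = ni, n2 = nj,
      z = z, q = q, p_value = p, significant = q > qcrit,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "q_critical") <- qcrit
  class(out) <- c("steel_dwass", "data.frame")
  out
}
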