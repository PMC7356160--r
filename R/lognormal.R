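#' Construct a lognormal weekly-intake model
#'
#' A `cd_lognormal` object holds the mean (`mu`) and standard deviation
#' (`sigma`) of log weekly intake, with fitting-method provenance. The
#' implied median intake is `exp(mu)`.
#'
#' @param mu mean of natural-log intake.
#' @param sigma sd of natural-log intake (>= 0; 0 is the degenerate
#'   point-mass limit, accepted for limiting arguments but rejected by the
#'   fitting functions).
#' @param method fitting-method tag.
#' @param n source sample size, if any.
#' @return an object of class `cd_lognormal`.
#' @export
lognormal_fit <- function(mu, sigma, method = "manual", n = NA_integer_) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma < 0)
    stop("mu must be finite and sigma nonnegative")
  structure(list(mu = mu, sigma = sigma, method = method, n = n),
            class = "cd_lognormal")
}

#' Fit a lognormal distribution by maximum likelihood
#'
#' `mu` is the mean and `sigma` the (n-1) standard deviation of the log
#' values. Intended for weekly intakes after outlier screening.
#'
#' @param values positive observations.
#' @return a `cd_lognormal` fit (`method = "mle"`).
#' @export
fit_lognormal_mle <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("nonpositive or non-finite value at index ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (length(values) < 2) stop("n >= 2 required")
  lv <- log(values)
  s <- stats::sd(lv)
  if (s == 0)
    stop("degenerate fit: all values identical (sigma = 0); mu would be ",
         format(mean(lv)))
  lognormal_fit(mean(lv), s, method = "mle", n = length(values))
}

#' Fit a lognormal distribution by quantile matching
#'
#' Recovers `(mu, sigma)` from a printed median and quartiles:
#' `mu = log(median)` and `sigma = log(q75/q25) / (2 * 0.67449)`, where
#' 0.67449 is the upper-quartile of the standard normal. Useful when only
#' summary quantiles are available.
#'
#' @param q25,median,q75 the 25th, 50th and 75th percentiles (all > 0 and
#'   strictly increasing).
#' @return a `cd_lognormal` fit (`method = "quantile_match"`).
#' @export
fit_lognormal_quantiles <- function(q25, median, q75) {
  if (!(q25 > 0 && q25 < median && median < q75))
    stop("quantiles must satisfy 0 < q25 < median < q75")
  z75 <- stats::qnorm(0.75)
  lognormal_fit(log(median), log(q75 / q25) / (2 * z75),
                method = "quantile_match")
}

#' @export
print.cd_lognormal <- function(x, ...) {
  cat(sprintf("Lognormal intake model (%s%s)\n", x$method,
              if (is.na(x$n)) "" else sprintf(", n = %d", x$n)))
  cat(sprintf("  mu = %.4f, sigma = %.4f  (median = %.3f)\n",
              x$mu, x$sigma, exp(x$mu)))
  invisible(x)
}

#' @export
coef.cd_lognormal <- function(object, ...) c(mu = object$mu,
                                             sigma = object$sigma)

#' Quantiles of a fitted lognormal intake model
#'
#' @param x a `cd_lognormal` fit.
#' @param probs probabilities.
#' @param ... unused.
#' @return quantiles on the intake scale.
#' @export
quantile.cd_lognormal <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                  ...) {
  stats::setNames(stats::qlnorm(probs, x$mu, x$sigma),
                  paste0(100 * probs, "%"))
}

#' Monte Carlo simulation from a lognormal intake model
#'
#' Draws `nsim` independent lognormal weekly intakes. With a seed the draws
#' are reproducible: identical seed, identical draws.
#'
#' @param object a `cd_lognormal` fit.
#' @param nsim number of repetitions (default 10,000).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param ... unused.
#' @return numeric vector of simulated weekly intakes (ug/kg BW/week), with
#'   the seed attached as attribute `seed`.
#' @export
simulate.cd_lognormal <- function(object, nsim = 10000, seed = NULL, ...) {
  if (nsim < 1) stop("nsim must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  draws <- if (object$sigma == 0) rep(exp(object$mu), nsim)
           else stats::rlnorm(nsim, object$mu, object$sigma)
  attr(draws, "seed") <- seed
  draws
}

#' Summarise a Monte Carlo simulation
#'
#' Median, 5th/95th percentiles and range of the simulated intakes
#' (quantile type 7, matching the cohort summaries).
#'
#' @param draws simulated values.
#' @return one-row `data.frame`: `n_reps`, `median`, `p5`, `p95`, `min`,
#'   `max`.
#' @export
summarize_simulation <- function(draws) {
  if (!length(draws)) stop("no draws to summarise")
  q <- stats::quantile(draws, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  data.frame(n_reps = length(draws), median = q[2], p5 = q[1], p95 = q[3],
             min = min(draws), max = max(draws))
}

#' Model-based TWI exceedance probability
#'
#' Upper-tail probability of the fitted lognormal at the tolerable weekly
#' intake: `1 - Phi((log(threshold) - mu) / sigma)`.
#'
#' @param fit a `cd_lognormal` fit.
#' @param threshold intake threshold (default TWI of 7 ug/kg BW/week).
#' @return exceedance probability in `[0, 1]`.
#' @export
tail_probability <- function(fit, threshold = 7) {
  if (threshold <= 0) stop("threshold must be positive")
  if (fit$sigma == 0) return(as.numeric(threshold <= exp(fit$mu)))
  stats::pnorm((log(threshold) - fit$mu) / fit$sigma, lower.tail = FALSE)
}

#' @describeIn lognormal_fit density curve of the fitted model with the
#'   TWI marked.
#' @param x a `cd_lognormal` fit.
#' @param twi threshold to mark.
#' @param ... further plot arguments.
#' @export
plot.cd_lognormal <- function(x, twi = 7, ...) {
  up <- stats::qlnorm(0.995, x$mu, x$sigma)
  grid <- seq(0.001, up, length.out = 400)
  graphics::plot(grid, stats::dlnorm(grid, x$mu, x$sigma), type = "l",
                 xlab = "ug/kg BW/week", ylab = "density",
                 main = "Fitted weekly Cd intake distribution", ...)
  graphics::abline(v = twi, lty = 2, col = "red3")
  invisible(x)
}
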