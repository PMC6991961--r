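#' Median-difference test via 0.5-quantile regression
#'
#' Compares the medians of two groups through a median (0.5-quantile)
#' regression of the pooled values on a group indicator. With a single
#' binary covariate the least-absolute-deviations fit has a closed form: the
#' intercept is the median of group A and the group coefficient is
#' `median(B) - median(A)` (midpoint convention for even counts).
#' Inference is a seeded nonparametric bootstrap of the coefficient
#' (resampling within each group): the two-sided p-value is the percentile
#' probability that the bootstrapped coefficient falls on the other side of
#' zero, `2 * min(P(b* <= 0), P(b* >= 0))` with add-one smoothing, and the
#' confidence interval is the percentile interval.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level for the percentile interval.
#' @return An object of class `chw_mediff`: list with `estimate` (median B
#'   minus median A), `p_value`, `ci_low`, `ci_high`, `n_boot`, `seed`,
#'   `n_a`, `n_b`.
#' @export
median_difference_test <- function(values_a, values_b, n_boot = 1000,
                                   seed = 1L, conf_level = 0.95) {
  values_a <- as.numeric(values_a[!is.na(values_a)])
  values_b <- as.numeric(values_b[!is.na(values_b)])
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  estimate <- stats::median(values_b) - stats::median(values_a)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  na <- length(values_a)
  nb <- length(values_b)
  boot_a <- matrix(sample(values_a, na * n_boot, replace = TRUE), nrow = na)
  boot_b <- matrix(sample(values_b, nb * n_boot, replace = TRUE), nrow = nb)
  coefs <- apply(boot_b, 2, stats::median) - apply(boot_a, 2, stats::median)

  if (stats::sd(coefs) == 0 && estimate == coefs[1]) {
    # degenerate bootstrap distribution (e.g. constant groups)
    p <- if (coefs[1] == 0) 1 else 2 / (n_boot + 1)
  } else {
    p_low <- (sum(coefs <= 0) + 1) / (n_boot + 1)
    p_high <- (sum(coefs >= 0) + 1) / (n_boot + 1)
    p <- min(1, 2 * min(p_low, p_high))
  }
  alpha <- 1 - conf_level
  ci <- stats::quantile(coefs, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  structure(list(estimate = estimate, p_value = p,
                 ci_low = min(ci[1], estimate),
                 ci_high = max(ci[2], estimate),
                 n_boot = n_boot, seed = seed, n_a = na, n_b = nb,
                 conf_level = conf_level),
            class = "chw_mediff")
}

#' @export
print.chw_mediff <- function(x, ...) {
  cat("Median difference (0.5-quantile regression, bootstrap inference)\n")
  cat(sprintf("  estimate: %.2f minutes (group B - group A; n = %d, %d)\n",
              x$estimate, x$n_a, x$n_b))
  cat(sprintf("  %.0f%% CI: [%.2f, %.2f]   p = %.4g  (%d bootstrap draws, seed %d)\n",
              100 * x$conf_level, x$ci_low, x$ci_high, x$p_value,
              x$n_boot, x$seed))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Overall rank-based test of whether several groups share a common
#' location, with the standard tie correction; the p-value comes from the
#' chi-square distribution with `k - 1` degrees of freedom. Wraps
#' [stats::kruskal.test()]. When every observation is identical the
#' statistic is defined as 0 with p = 1.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List with `H` (tie-corrected statistic), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1) {
    return(list(H = 0, df = length(groups) - 1L, p_value = 1,
                n = length(x)))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(x))
}

#' Two-sample test of proportions
#'
#' Two-sided pooled z-test of `x1/n1` versus `x2/n2` without continuity
#' correction (the squared statistic is the 1-df chi-square statistic of the
#' 2x2 table).
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `p1`, `p2`, `z`, `p_value`, `n1`, `n2`.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be >= 1", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(p1 = p1, p2 = p2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2)
}
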