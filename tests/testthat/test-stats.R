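test_that("median difference test handles identical and constant groups", {
  same <- median_difference_test(c(10, 20, 30), c(10, 20, 30), seed = 1)
  expect_equal(same$estimate, 0)
  expect_gt(same$p_value, 0.5)
  expect_true(same$ci_low <= same$estimate & same$estimate <= same$ci_high)

  shift <- median_difference_test(c(10, 10, 10), c(20, 20, 20), seed = 1)
  expect_equal(shift$estimate, 10)
  expect_lt(shift$p_value, 0.01)

  degen <- median_difference_test(c(5, 5, 5), c(5, 5, 5), seed = 1)
  expect_equal(degen$estimate, 0)
  expect_equal(degen$p_value, 1)

  expect_error(median_difference_test(1, c(1, 2)), "at least 2")
})

test_that("a true median shift of 20 is detected and estimated", {
  set.seed(123)
  a <- round(exp(log(40) + 0.5 * rnorm(200)))
  b <- round(exp(log(60) + 0.5 * rnorm(200)))
  res <- median_difference_test(a, b, n_boot = 1000, seed = 99)
  expect_lt(abs(res$estimate - 20), 3)
  expect_lt(res$p_value, 0.01)
  expect_true(res$ci_low <= res$estimate & res$estimate <= res$ci_high)
})

test_that("closed-form group coefficient solves the LAD problem", {
  set.seed(7)
  for (i in 1:5) {
    a <- sample(5:60, 7, replace = TRUE)
    b <- sample(5:80, 6, replace = TRUE)
    est <- median_difference_test(a, b, n_boot = 99, seed = 1)$estimate
    brute <- lad_brute_force(a, b)
    closed_obj <- sum(abs(a - median(a))) + sum(abs(b - median(a) - est))
    # the closed form attains the brute-force optimum
    expect_lt(closed_obj, brute$objective + 1e-9)
  }
})

test_that("kruskal_wallis matches the rank formula and base equivalences", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$p_value, 1)

  g3 <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(g3)
  expect_equal(res$H, kw_rank_formula(g3), tolerance = 1e-12)
  expect_equal(res$df, 2)

  const <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(const$H, 0)
  expect_equal(const$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("kruskal_wallis equals the brute-force oracle on exhaustive small instances", {
  # every 2-group split (both groups non-empty) of small multisets with ties
  multisets <- list(c(1, 1, 2, 2, 3, 3), c(1, 2, 3, 4, 5, 6, 7),
                    c(1, 1, 1, 2, 5, 5, 9, 9), c(2, 2, 2, 2, 3))
  for (vals in multisets) {
    n <- length(vals)
    for (mask in 1:(2^n - 2)) {
      sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      g <- list(vals[sel], vals[!sel])
      h_oracle <- kw_rank_formula(g)
      if (length(unique(vals)) == 1) h_oracle <- 0
      expect_equal(kruskal_wallis(g)$H, h_oracle, tolerance = 1e-10)
    }
  }
})

test_that("two-group kruskal_wallis agrees with the rank-sum test", {
  set.seed(31)
  a <- sample(1000, 12)  # tie-free
  b <- sample(2000:5000, 9)
  kw <- kruskal_wallis(list(a, b))
  w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(kw$p_value, w$p.value, tolerance = 1e-10)
})

test_that("proportion_test is the pooled z-test without correction", {
  eq <- proportion_test(50, 100, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  expect_lt(proportion_test(0, 10, 10, 10)$p_value, 0.001)

  pt <- proportion_test(30, 100, 45, 100)
  chi <- chisq.test(matrix(c(30, 70, 45, 55), nrow = 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(pt$z^2, unname(chi$statistic), tolerance = 1e-9)
  expect_equal(pt$p_value, chi$p.value, tolerance = 1e-9)

  expect_error(proportion_test(1, 0, 1, 2), ">= 1")
  expect_error(proportion_test(5, 4, 1, 2), "0 <= x <= n")
})

test_that("z squared equals the 2x2 chi-square statistic across random tables", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    if ((x1 + x2) == 0 || (x1 + x2) == (n1 + n2)) next
    pt <- proportion_test(x1, n1, x2, n2)
    chi <- suppressWarnings(
      chisq.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE),
                 correct = FALSE))
    expect_equal(pt$z^2, unname(chi$statistic), tolerance = 1e-9)
  }
})
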