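test_that("fractional ranks follow the weighted midpoint convention", {
  expect_equal(fractional_rank(c(10, 20, 30)), c(1/6, 1/2, 5/6))
  expect_equal(fractional_rank(c(10, 10, 20)), c(1/3, 1/3, 5/6))
  expect_equal(fractional_rank(c(1, 2), weights = c(0.25, 0.75)),
               c(0.125, 0.625))
  # permutation invariance with ties
  x <- c(5, 3, 3, 8, 5)
  perm <- c(4, 1, 5, 2, 3)
  expect_equal(fractional_rank(x)[perm], fractional_rank(x[perm]))
})

test_that("weighted mean rank is exactly 0.5, with and without ties", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(2:80, 1)
    income <- sample(1:20, n, replace = TRUE)  # many ties
    w <- rgamma(n, 2, 1)
    r <- fractional_rank(income, w)
    expect_equal(sum(w * r) / sum(w), 0.5, tolerance = 1e-12)
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("the index reproduces hand-computed and closed-form values", {
  expect_equal(concentration_index(c(5, 5, 5), income = c(1, 2, 3),
                                   se_method = "none")$index, 0)
  expect_equal(concentration_index(c(1, 2, 3), income = c(10, 20, 30),
                                   se_method = "none")$index,
               2 / 9, tolerance = 1e-12)
  # Y = 1{R > 0.5} on a dense uniform rank grid -> 0.5
  n <- 20001
  r <- (seq_len(n) - 0.5) / n
  y <- as.numeric(r > 0.5)
  expect_equal(concentration_index(y, rank = r)$index, 0.5,
               tolerance = 2e-3)
})

test_that("covariance, direct-sum and regression forms agree", {
  set.seed(31)
  for (i in 1:60) {
    inst <- random_ranked_instance()
    ci <- concentration_index(inst$y, income = inst$income)
    expect_equal(ci$index, ci_direct_sum(inst$y, inst$income),
                 tolerance = 1e-12)
    expect_equal(ci$index, ci_regression_slope(inst$y, inst$income),
                 tolerance = 1e-10)
  }
})

test_that("the index is scale invariant and negates under rank reversal", {
  set.seed(41)
  for (i in 1:20) {
    inst <- random_ranked_instance(n = 100)
    r <- fractional_rank(inst$income)
    a <- concentration_index(inst$y, rank = r)$index
    expect_equal(concentration_index(7.3 * inst$y, rank = r)$index, a,
                 tolerance = 1e-12)
    expect_equal(concentration_index(inst$y, rank = 1 - r)$index, -a,
                 tolerance = 1e-12)
  }
})

test_that("a binary outcome obeys the attainable bound |C| <= 1 - mu", {
  # extremal configuration: all cases in the poorest (or richest) k units
  for (n in c(10, 50, 200)) {
    income <- seq_len(n)
    for (k in c(1, floor(n / 4), floor(n / 2))) {
      y_poor <- c(rep(1, k), rep(0, n - k))
      y_rich <- rev(y_poor)
      mu <- k / n
      for (y in list(y_poor, y_rich)) {
        ci <- concentration_index(y, income = income)$index
        expect_lte(abs(ci), 1 - mu + 1e-12)
      }
    }
  }
})

test_that("the analytic interval matches the regression-slope standard error", {
  set.seed(51)
  inst <- random_ranked_instance(n = 300)
  ci <- concentration_index(inst$y, income = inst$income)
  r <- fractional_rank(inst$income)
  s2 <- mean((r - mean(r))^2)
  fit <- lm(2 * s2 * inst$y / mean(inst$y) ~ r)
  expect_equal(ci$se, summary(fit)$coefficients["r", "Std. Error"],
               tolerance = 1e-10)
  expect_lt(ci$ci_low, ci$index)
  expect_gt(ci$ci_high, ci$index)
})

test_that("concentration curves have exact endpoints and match the index", {
  # constant outcome: the diagonal
  curve <- concentration_curve(rep(2, 5), income = 1:5)
  expect_equal(curve$L, curve$p, tolerance = 1e-12)
  # all mass on the poorest of 4 equal units
  curve <- concentration_curve(c(1, 0, 0, 0), income = 1:4)
  expect_equal(curve$L[curve$p == 0.25], 1)
  expect_equal(curve$p[1], 0); expect_equal(curve$L[1], 0)
  expect_equal(curve$p[nrow(curve)], 1); expect_equal(curve$L[nrow(curve)], 1)
  expect_true(all(diff(curve$p) >= 0) && all(diff(curve$L) >= -1e-12))

  set.seed(61)
  for (i in 1:20) {
    inst <- random_ranked_instance(n = 400)
    idx <- concentration_index(inst$y, income = inst$income)$index
    curve <- concentration_curve(inst$y, income = inst$income,
                                 n_points = 1e4)
    expect_equal(curve_index(curve), idx, tolerance = 1e-3)
    # the curve lies above the diagonal (on signed average) iff the index is
    # negative: the signed area between curve and diagonal is -C/2
    gap <- curve$L - curve$p
    signed_area <- sum(diff(curve$p) * (head(gap, -1) + tail(gap, -1)) / 2)
    expect_equal(signed_area, -idx / 2, tolerance = 1e-3)
    if (idx < -0.02) {
      expect_gt(signed_area, 0)
      expect_gt(mean(gap > 0), 0.5)
    }
    if (idx > 0.02) {
      expect_lt(signed_area, 0)
      expect_gt(mean(gap < 0), 0.5)
    }
  }
})

test_that("the bootstrap interval is seeded, reproducible and degenerate-safe", {
  set.seed(71)
  y <- rbinom(200, 1, 0.3); income <- exp(rnorm(200, 9, 1))
  a <- bootstrap_ci(y, income, n_reps = 200, seed = 5)
  b <- bootstrap_ci(y, income, n_reps = 200, seed = 5)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_equal(a$method, "bootstrap")
  expect_error(bootstrap_ci(y, income, n_reps = 50, seed = 1), "n_reps")

  const <- bootstrap_ci(rep(3, 50), income = exp(rnorm(50)),
                        n_reps = 100, seed = 2)
  expect_equal(const$ci_low, 0)
  expect_equal(const$ci_high, 0)

  # nearly-degenerate outcome: redraws are counted and warned about
  y2 <- c(1, rep(0, 29))
  expect_warning(res <- bootstrap_ci(y2, income = 1:30, n_reps = 100,
                                     seed = 3), "degenerate")
  expect_gt(res$n_degenerate, 0)
})

test_that("bootstrap intervals cover a known large-sample index", {
  # replicate small panels from one generating process; the large-sample
  # index is estimated once at high n
  big <- small_panel(n = 20000, seed = 123, n_waves = 1)
  flag_big <- flag_che(big)
  truth <- concentration_index(flag_big, income = big$income,
                               se_method = "none")$index
  hits <- 0L
  n_rep <- 20L
  for (k in seq_len(n_rep)) {
    pan <- small_panel(n = 500, seed = 3000 + k, n_waves = 1)
    fl <- flag_che(pan)
    ci <- bootstrap_ci(fl, pan$income, n_reps = 200, seed = k)
    if (ci$ci_low <= truth && truth <= ci$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 15L)  # nominal 95%; small-n and MC slack allowed
})

test_that("degenerate inputs raise clear errors", {
  expect_error(concentration_index(c(0, 0, 0), income = 1:3), "mean is zero")
  expect_error(concentration_index(1, income = 1), "at least 2")
  expect_error(fractional_rank(c(1, Inf)), "finite")
  expect_error(fractional_rank(1:3, weights = c(1, -1, 1)), "positive")
  expect_error(fractional_rank(1:3, weights = 1:2), "length")
})
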