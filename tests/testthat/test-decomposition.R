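test_that("probit recovers simulated coefficients within 3 standard errors", {
  set.seed(81)
  n <- 20000
  x <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  eta <- -0.2 + 0.5 * x[, 1] - 0.3 * x[, 2]
  y <- rbinom(n, 1, pnorm(eta))
  fit <- fit_probit(x, y)
  se <- sqrt(diag(chol2inv(fit$glm_fit$qr$qr[1:3, 1:3])))
  expect_lt(abs(fit$coefficients["x1"] - 0.5), 3 * se[2])
  expect_lt(abs(fit$coefficients["x2"] + 0.3), 3 * se[3])
  # AME has the same sign as the latent coefficient and |AME| < |beta|
  expect_gt(fit$marginal_effects["x1"], 0)
  expect_lt(fit$marginal_effects["x2"], 0)
  expect_lt(abs(fit$marginal_effects["x1"]), abs(fit$coefficients["x1"]))
})

test_that("a null model yields marginal effects near zero", {
  set.seed(82)
  n <- 20000
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.3)
  fit <- fit_probit(x, y)
  expect_lt(max(abs(fit$marginal_effects)), 0.02)
})

test_that("design validation rejects constants, collinearity and one-class outcomes", {
  set.seed(83)
  x <- cbind(good = rnorm(50), flat = rep(1, 50))
  y <- rbinom(50, 1, 0.5)
  expect_error(fit_probit(x, y), "flat")
  expect_error(fit_probit(cbind(g = rnorm(50)), rep(1, 50)), "single class")
  x2 <- cbind(a = rnorm(50))
  x2 <- cbind(x2, b = 2 * x2[, 1])
  expect_error(fit_probit(x2, y), "rank deficient")
})

test_that("perfect separation is reported with the offending column", {
  x <- cbind(sep = c(rep(0, 25), rep(1, 25)), noise = rnorm(50))
  y <- c(rep(0, 25), rep(1, 25))
  expect_error(fit_probit(x, y), "sep")
})

test_that("the decomposition identity holds to 1e-10 and percents are consistent", {
  for (seed in c(5, 17)) {
    panel <- small_panel(n = 600, seed = seed)
    for (w in c(2013, 2018)) {
      d <- suppressWarnings(decompose_cindex(panel[panel$wave == w, ]))
      expect_lt(abs(d$total - sum(d$rows$contribution) - d$residual), 1e-10)
      expect_equal(sum(d$rows$percent) + d$residual_percent, 100,
                   tolerance = 1e-8)
      expect_equal(sum(d$rows$percent_excl_residual), 100, tolerance = 1e-8)
      # contribution = elasticity x covariate index, exactly
      expect_equal(d$rows$contribution,
                   d$rows$elasticity * d$rows$cindex, tolerance = 1e-14)
    }
  }
})

test_that("covariate concentration indices match the inequality module", {
  panel <- small_panel(n = 500, seed = 29)
  sub <- panel[panel$wave == 2015, ]
  d <- suppressWarnings(decompose_cindex(sub))
  r <- d$rank
  for (j in sample(seq_len(nrow(d$rows)), 5)) {
    v <- d$rows$variable[j]
    x <- che_design(sub)$x[, v]
    expect_equal(d$rows$cindex[j],
                 concentration_index(x, rank = r, se_method = "none")$index,
                 tolerance = 1e-12)
  }
})

test_that("economic status dominates when CHE is driven by income quintiles only", {
  set.seed(85)
  n <- 50000
  income <- exp(rnorm(n, 9.5, 0.8))
  q <- quantile(income, seq(0.2, 0.8, 0.2), names = FALSE)
  econ <- findInterval(income, q)  # 0 = lowest ... 4 = highest
  eta <- -0.3 - 0.35 * econ
  y <- rbinom(n, 1, pnorm(eta))
  x <- cbind(
    econ_lower = as.numeric(econ == 1), econ_middle = as.numeric(econ == 2),
    econ_higher = as.numeric(econ == 3), econ_highest = as.numeric(econ == 4),
    noise_a = rbinom(n, 1, 0.5), noise_b = rgamma(n, 2, 1))
  d <- decompose_cindex(x = x, y = y, income = income,
                        families = list(economic_status = colnames(x)[1:4],
                                        noise = colnames(x)[5:6]))
  expect_lt(d$total, 0)
  expect_gt(d$group_totals[["economic_status"]], 80)
  expect_lt(abs(d$group_totals[["noise"]]), 5)
})

test_that("group contributions sum member percents and flag unknown members", {
  vals <- c(a = 1.5, b = -0.5, c = 10)
  expect_equal(group_contributions(vals, list(ab = c("a", "b")))[["ab"]], 1)
  expect_equal(group_contributions(vals, list(solo = "c"))[["solo"]], 10)
  expect_error(group_contributions(vals, list(bad = c("a", "zzz"))), "zzz")
})

test_that("published decomposition columns are internally consistent", {
  # reference percent contributions from the emulated survey's published
  # baseline-year decomposition table
  printed_2013 <- c(
    econ_lower = 1.36, econ_middle = -0.05, econ_higher = 15.41,
    econ_highest = 56.78,
    age_51_60 = -11.68, age_61_70 = 2.62, age_ge71 = 34.19)
  fam <- list(economic_status = c("econ_lower", "econ_middle",
                                  "econ_higher", "econ_highest"),
              age = c("age_51_60", "age_61_70", "age_ge71"))
  totals <- group_contributions(printed_2013, fam)
  expect_equal(unname(totals["economic_status"]), 73.50)
  expect_equal(unname(totals["age"]), 25.13)
})

test_that("at-means marginal effects are offered and differ from the average", {
  panel <- small_panel(n = 500, seed = 31)
  sub <- panel[panel$wave == 2013, ]
  a <- suppressWarnings(decompose_cindex(sub, me_type = "average"))
  b <- suppressWarnings(decompose_cindex(sub, me_type = "at_means"))
  expect_false(isTRUE(all.equal(a$rows$marginal_effect,
                                b$rows$marginal_effect)))
  # the identity still holds in the at-means mode
  expect_lt(abs(b$total - sum(b$rows$contribution) - b$residual), 1e-10)
})
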