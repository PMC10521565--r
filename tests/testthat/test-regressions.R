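test_that("the logistic OR for a lone binary predictor equals the cross-product ratio", {
  # 2x2 table: exposed cases a=10, exposed non-cases b=20,
  # unexposed cases c=20, unexposed non-cases d=10 -> OR = ad/bc = 0.25
  x <- cbind(exposed = c(rep(1, 30), rep(0, 30)))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  fit <- fit_che_logistic(x = x, y = y)
  expect_equal(fit$table$or, 0.25, tolerance = 1e-8)
  expect_lt(fit$table$ci_low, 0.25)
  expect_gt(fit$table$ci_high, 0.25)
})

test_that("an independent predictor gives an odds ratio near one", {
  set.seed(91)
  n <- 20000
  x <- cbind(z = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.25)
  fit <- fit_che_logistic(x = x, y = y)
  se <- summary(fit$glm_fit)$coefficients[2, "Std. Error"]
  expect_lt(abs(log(fit$table$or)), 3 * se)
})

test_that("a simulated wave shift in log-odds is recovered", {
  set.seed(92)
  n <- 20000
  wave18 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1.2 + 0.378 * wave18))
  fit <- fit_che_logistic(x = cbind(wave_2018 = wave18), y = y)
  se <- summary(fit$glm_fit)$coefficients[2, "Std. Error"]
  expect_lt(abs(log(fit$table$or) - 0.378), 3 * se)
})

test_that("the panel interface adds wave dummies and reports all determinants", {
  panel <- small_panel(n = 400, seed = 13)
  fit <- suppressWarnings(fit_che_logistic(panel))
  expect_true(all(c("wave_2015", "wave_2018") %in% fit$table$variable))
  expect_true(all(fit$table$or > 0))
  expect_true(all(fit$table$ci_low <= fit$table$or &
                  fit$table$or <= fit$table$ci_high))
})

test_that("noise-free linear data are interpolated exactly at every quantile", {
  x <- cbind(x = seq_len(30))
  y <- 1 + 2 * seq_len(30)
  for (tau in c(0.25, 0.5, 0.75)) {
    fit <- fit_quantile(x, y, tau = tau, n_boot = 0)
    expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-6)
    expect_lt(fit$objective, 1e-6)
  }
})

test_that("median regression is consistent under symmetric noise", {
  set.seed(93)
  n <- 10000
  x <- rnorm(n)
  y <- 1 + 2 * x + rt(n, df = 5)
  fit <- fit_quantile(cbind(x = x), y, tau = 0.5, n_boot = 100, seed = 4)
  expect_lt(abs(coef(fit)[["x"]] - 2), 0.1)
  expect_gte(2, fit$ci["x", 1])
  expect_lte(2, fit$ci["x", 2])
})

test_that("the pinball objective is a local minimum against perturbations", {
  set.seed(94)
  n <- 400
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- 2 + x[, 1] - 0.5 * x[, 2] + rexp(n) - 1
  for (tau in c(0.25, 0.75)) {
    fit <- fit_quantile(x, y, tau = tau, n_boot = 0)
    beta <- coef(fit)
    X <- cbind(1, x)
    scale <- pmax(abs(beta), 0.1)
    for (k in 1:100) {
      pert <- beta + rnorm(length(beta)) * scale * 0.05
      expect_lte(fit$objective,
                 cheineq:::pinball_loss(y - drop(X %*% pert), tau) + 1e-8)
    }
  }
})

test_that("quantile fits are equivariant to positive rescaling of the response", {
  set.seed(95)
  n <- 500
  x <- cbind(x = rnorm(n))
  y <- 3 + x[, 1] + rnorm(n)
  a <- fit_quantile(x, y, tau = 0.25, n_boot = 0)
  b <- fit_quantile(x, 10 * y, tau = 0.25, n_boot = 0)
  expect_equal(unname(coef(b)), 10 * unname(coef(a)), tolerance = 1e-3)
})

test_that("CHE households show negative income coefficients across quantiles", {
  # multiplicative income penalty for CHE households: coefficient negative at
  # every tau and increasingly negative with tau
  set.seed(96)
  n <- 6000
  che <- rbinom(n, 1, 0.25)
  base <- exp(rnorm(n, 9.5, 0.6))
  income <- base * ifelse(che == 1, 0.6, 1)
  fit25 <- fit_quantile(cbind(che = che), income, tau = 0.25, n_boot = 0)
  fit50 <- fit_quantile(cbind(che = che), income, tau = 0.50, n_boot = 0)
  fit75 <- fit_quantile(cbind(che = che), income, tau = 0.75, n_boot = 0)
  cs <- c(coef(fit25)[["che"]], coef(fit50)[["che"]], coef(fit75)[["che"]])
  expect_true(all(cs < 0))
  expect_true(all(diff(cs) < 0))
})

test_that("degenerate quantile designs are rejected", {
  expect_error(fit_quantile(cbind(a = 1:3), 1:3, tau = 1.2), "tau")
  x <- cbind(a = rnorm(20))
  expect_error(fit_quantile(cbind(x, b = 2 * x[, 1]), rnorm(20), tau = 0.5),
               "degenerate|collinear")
  expect_error(fit_quantile(cbind(a = 1:3), 1:4, tau = 0.5), "differ")
})
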