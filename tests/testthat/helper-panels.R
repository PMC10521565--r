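# shared fixtures, all generated in code

small_panel <- function(n = 300, seed = 11, ...) {
  generate_panel(panel_config(n_households = n, seed = seed, ...))
}

# a random non-negative outcome with incomes, for index oracle checks
random_ranked_instance <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:500, 1)
  kind <- sample(c("binary", "count", "continuous"), 1)
  y <- switch(kind,
              binary = rbinom(n, 1, runif(1, 0.05, 0.95)),
              count = rpois(n, runif(1, 0.5, 5)),
              continuous = rgamma(n, 2, 1))
  if (sum(y) == 0) y[sample(n, 1)] <- 1
  income <- exp(rnorm(n, 9, 1))
  # occasionally force ties in income
  if (runif(1) < 0.3) income <- round(income, -2) + 1
  list(y = y, income = income)
}

# direct sum form of the concentration index: equal weights, midpoint ranks
ci_direct_sum <- function(y, income) {
  n <- length(y)
  r <- fractional_rank(income)
  2 / (n * mean(y)) * sum(y * r) - 1
}

# convenient-regression slope, computed independently via lm on raw data
ci_regression_slope <- function(y, income) {
  r <- fractional_rank(income)
  s2 <- mean((r - mean(r))^2)
  unname(coef(lm(2 * s2 * y / mean(y) ~ r))[2])
}
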