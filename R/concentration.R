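#' Weighted fractional income ranks
#'
#' Maps each unit's position in the income ordering to (0, 1) using the
#' weighted midpoint convention: sorting by income ascending, unit i receives
#' rank (cumulative weight before i + w_i / 2) / total weight. Tied incomes
#' receive their group's weighted midpoint, which equals the average of the
#' members' midpoint ranks; the result is deterministic and
#' permutation-invariant, and the weighted mean rank is exactly 0.5.
#'
#' `mode = "order"` instead assigns the raw order statistic i/N (equal
#' weights only), provided for sensitivity analysis; its mean is not 0.5 and
#' it slightly biases the covariance form of the concentration index.
#'
#' @param income numeric vector of household incomes (finite).
#' @param weights optional positive weights, default 1.
#' @param mode `"midpoint"` (default) or `"order"`.
#' @return numeric vector of ranks in (0, 1), aligned with `income`.
#' @export
#' @examples
#' fractional_rank(c(10, 20, 30))          # 1/6, 1/2, 5/6
#' fractional_rank(c(10, 10, 20))          # ties share 1/3
fractional_rank <- function(income, weights = NULL,
                            mode = c("midpoint", "order")) {
  mode <- match.arg(mode)
  n <- length(income)
  if (n < 1L) stop("empty income vector", call. = FALSE)
  if (any(!is.finite(income))) stop("incomes must be finite", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("income and weights lengths differ", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)

  ord <- order(income)
  if (mode == "order") {
    r <- numeric(n)
    r[ord] <- seq_len(n) / n
    return(r)
  }
  w <- weights[ord]
  W <- sum(w)
  cum_before <- cumsum(w) - w
  mid <- (cum_before + w / 2) / W
  # ties: weighted group midpoint = (weight before group + group weight/2)/W
  x <- income[ord]
  grp <- cumsum(!duplicated(x))
  grp_w <- tapply(w, grp, sum)
  grp_before <- tapply(cum_before, grp, min)
  mid <- as.numeric((grp_before[grp] + grp_w[grp] / 2) / W)
  r <- numeric(n)
  r[ord] <- mid
  r
}

#' Concentration index of an outcome over income ranks
#'
#' Computes the concentration index C = (2 / mu) * cov_w(Y, R), where Y is a
#' non-negative outcome (here typically the CHE flag), R the weighted
#' fractional income rank, and mu the weighted mean of Y. A negative index
#' means the outcome is concentrated among poorer households. Uncertainty is
#' by the convenient-regression method (the slope standard error of the
#' weighted regression of 2 * var_w(R) * Y / mu on R, whose point estimate
#' equals C exactly) or by household-level bootstrap via [bootstrap_ci()].
#'
#' @param outcome non-negative numeric vector (length >= 2).
#' @param income household income used for ranking; ignored if `rank` given.
#' @param rank precomputed fractional ranks in (0, 1).
#' @param weights optional positive weights.
#' @param se_method `"regression"` (default) or `"none"`.
#' @param rank_mode passed to [fractional_rank()] when ranks are computed.
#' @param normalisation `"none"` (default, the plain index), `"wagstaff"`
#'   (divide by 1 - mu; binary outcomes) or `"erreygers"` (the correction
#'   4 * mu * C for outcomes bounded in `[0, 1]`). Corrections are applied to
#'   the index and its interval and labelled in the result.
#' @return object of class `concindex` with fields `index`, `se`, `ci_low`,
#'   `ci_high`, `mu`, `n`, `method`, and the ranked inputs.
#' @export
#' @examples
#' ci <- concentration_index(c(1, 2, 3), income = c(10, 20, 30))
#' ci$index  # 2/9
concentration_index <- function(outcome, income = NULL, rank = NULL,
                                weights = NULL,
                                se_method = c("regression", "none"),
                                rank_mode = c("midpoint", "order"),
                                normalisation = c("none", "wagstaff",
                                                  "erreygers")) {
  se_method <- match.arg(se_method)
  normalisation <- match.arg(normalisation)
  n <- length(outcome)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(outcome)) || any(outcome < 0))
    stop("outcome must be finite and non-negative", call. = FALSE)
  if (is.null(rank)) {
    if (is.null(income))
      stop("supply either income or rank", call. = FALSE)
    rank <- fractional_rank(income, weights, mode = match.arg(rank_mode))
  }
  if (length(rank) != n)
    stop("outcome and rank lengths differ", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)

  mu <- sum(w * outcome)
  if (mu <= 0)
    stop("undefined concentration index: outcome mean is zero", call. = FALSE)
  rbar <- sum(w * rank)
  cov_wr <- sum(w * (outcome - mu) * (rank - rbar))
  index <- 2 / mu * cov_wr

  se <- NA_real_
  if (se_method == "regression") {
    var_r <- sum(w * (rank - rbar)^2)
    lhs <- 2 * var_r * outcome / mu
    fit <- stats::lm(lhs ~ rank, weights = w)
    se <- summary(fit)$coefficients["rank", "Std. Error"]
  }

  scale_fac <- switch(normalisation,
                      none = 1,
                      wagstaff = 1 / (1 - mu),
                      erreygers = 4 * mu)
  index <- index * scale_fac
  se <- se * scale_fac
  z <- stats::qnorm(0.975)
  res <- list(index = index, se = se,
              ci_low = if (is.na(se)) NA_real_ else index - z * se,
              ci_high = if (is.na(se)) NA_real_ else index + z * se,
              mu = mu, n = n,
              method = if (se_method == "none") "point" else "analytic",
              normalisation = normalisation,
              outcome = outcome, rank = rank, weights = weights)
  class(res) <- "concindex"
  res
}

#' @export
print.concindex <- function(x, digits = 4, ...) {
  lab <- switch(x$normalisation, none = "Concentration index",
                wagstaff = "Wagstaff-normalised concentration index",
                erreygers = "Erreygers-corrected concentration index")
  cat(sprintf("%s: %.*f", lab, digits, x$index))
  if (!is.na(x$se))
    cat(sprintf("  (SE %.*f, 95%% CI %.*f, %.*f; %s)",
                digits, x$se, digits, x$ci_low, digits, x$ci_high, x$method))
  cat(sprintf("\n  n = %d, outcome mean = %.*f\n", x$n, digits, x$mu))
  invisible(x)
}

#' @export
summary.concindex <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.concindex <- function(object, ...) c(index = object$index)

#' @export
confint.concindex <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  matrix(c(object$index - z * object$se, object$index + z * object$se),
         nrow = 1, dimnames = list("index",
                                   paste0(c((1 - level) / 2,
                                            1 - (1 - level) / 2) * 100, " %")))
}

#' Concentration curve
#'
#' Cumulative outcome share against cumulative population share, with the
#' population ranked poorest to richest. The curve includes the exact
#' endpoints (0, 0) and (1, 1); it lies above the 45-degree diagonal when the
#' outcome is concentrated among the poor (negative index), and
#' 1 - 2 * (area under the curve) equals the concentration index up to
#' quadrature error.
#'
#' @inheritParams concentration_index
#' @param n_points optional number of interpolation points; by default one
#'   point per distinct rank.
#' @return object of class `conc_curve`: a data frame with columns `p`
#'   (population share) and `L` (outcome share).
#' @export
concentration_curve <- function(outcome, income = NULL, rank = NULL,
                                weights = NULL, n_points = NULL,
                                rank_mode = c("midpoint", "order")) {
  n <- length(outcome)
  if (any(!is.finite(outcome)) || any(outcome < 0))
    stop("outcome must be finite and non-negative", call. = FALSE)
  if (is.null(rank)) {
    if (is.null(income)) stop("supply either income or rank", call. = FALSE)
    rank <- fractional_rank(income, weights, mode = match.arg(rank_mode))
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(weights * outcome) <= 0)
    stop("undefined concentration curve: outcome mean is zero", call. = FALSE)

  ord <- order(rank)
  w <- weights[ord] / sum(weights)
  y <- outcome[ord]
  r <- rank[ord]
  # aggregate tied ranks: the curve's knots are rank groups, so the area
  # identity with the tie-averaged index is exact regardless of within-tie
  # ordering
  grp <- cumsum(!duplicated(r))
  w_g <- as.numeric(tapply(w, grp, sum))
  yw_g <- as.numeric(tapply(w * y, grp, sum))
  p <- c(0, cumsum(w_g))
  L <- c(0, cumsum(yw_g) / sum(yw_g))
  p[length(p)] <- 1; L[length(L)] <- 1
  if (!is.null(n_points)) {
    grid <- seq(0, 1, length.out = n_points + 1L)
    L <- stats::approx(p, L, xout = grid, ties = "ordered")$y
    p <- grid
  }
  curve <- data.frame(p = p, L = L)
  class(curve) <- c("conc_curve", "data.frame")
  curve
}

#' Area-based index implied by a concentration curve
#'
#' Trapezoidal quadrature of 1 - 2 * area under the curve; matches the
#' covariance-form concentration index up to quadrature error.
#'
#' @param curve a `conc_curve`.
#' @return numeric scalar.
#' @export
curve_index <- function(curve) {
  stopifnot(inherits(curve, "conc_curve"))
  area <- sum(diff(curve$p) * (utils::head(curve$L, -1) +
                               utils::tail(curve$L, -1)) / 2)
  1 - 2 * area
}

#' @export
plot.conc_curve <- function(x, ...) {
  plot(x$p, x$L, type = "l", xlab = "Cumulative population share (poorest first)",
       ylab = "Cumulative outcome share", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Bootstrap confidence interval for the concentration index
#'
#' Household-level resampling with replacement; ranks are recomputed within
#' each resample. Resamples with an all-zero outcome (undefined index) are
#' redrawn, counted, and reported with a warning.
#'
#' @inheritParams concentration_index
#' @param n_reps number of bootstrap replicates (>= 100).
#' @param seed integer seed for reproducibility.
#' @return object of class `concindex` with a percentile 95% interval and
#'   `method = "bootstrap"`.
#' @export
bootstrap_ci <- function(outcome, income, weights = NULL, n_reps = 1000L,
                         seed = 1L, rank_mode = c("midpoint", "order")) {
  if (n_reps < 100L) stop("n_reps must be >= 100", call. = FALSE)
  rank_mode <- match.arg(rank_mode)
  n <- length(outcome)
  if (length(income) != n)
    stop("outcome and income lengths differ", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)

  point <- concentration_index(outcome, income = income, weights = weights,
                               se_method = "none", rank_mode = rank_mode)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  reps <- numeric(n_reps)
  n_degenerate <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(weights[idx] * outcome[idx]) > 0) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 100L * n_reps)
        stop("bootstrap degenerate: outcome almost surely all zero",
             call. = FALSE)
    }
    reps[b] <- concentration_index(outcome[idx], income = income[idx],
                                   weights = weights[idx],
                                   se_method = "none",
                                   rank_mode = rank_mode)$index
  }
  if (n_degenerate > 0L)
    warning(n_degenerate, " degenerate resample(s) redrawn", call. = FALSE)

  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  res <- point
  res$se <- stats::sd(reps)
  res$ci_low <- qs[1]
  res$ci_high <- qs[2]
  res$method <- "bootstrap"
  res$n_reps <- n_reps
  res$n_degenerate <- n_degenerate
  res
}
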