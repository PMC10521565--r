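#' Pooled logistic regression odds ratios for CHE determinants
#'
#' Pools all waves with wave fixed effects (reference: the first wave) and
#' fits a maximum-likelihood logistic regression of the CHE flag on the
#' standard determinant design ([che_design()], with economic-status
#' quintiles computed within wave). Odds ratios are exp(coefficient) with
#' Wald 95% intervals.
#'
#' @param panel a `che_panel` data frame covering one or more waves.
#' @param config a [che_config()].
#' @param x,y optional explicit design matrix and 0/1 outcome, bypassing the
#'   panel interface (no wave dummies are added in that case).
#' @return object of class `che_logistic`: data frame `table` with columns
#'   `variable`, `or`, `ci_low`, `ci_high`, plus the underlying `glm` fit.
#' @export
fit_che_logistic <- function(panel = NULL, config = che_config(),
                             x = NULL, y = NULL) {
  if (!is.null(panel)) {
    flag <- flag_che(panel, config)
    keep <- !is.na(flag)
    panel <- panel[keep, , drop = FALSE]
    y <- flag[keep]
    parts <- lapply(split(seq_len(nrow(panel)), panel$wave), function(idx) {
      des <- che_design(panel[idx, , drop = FALSE])
      list(idx = idx, x = des$x)
    })
    x <- matrix(NA_real_, nrow(panel), ncol(parts[[1]]$x),
                dimnames = list(NULL, colnames(parts[[1]]$x)))
    for (p in parts) x[p$idx, ] <- p$x
    waves <- sort(unique(panel$wave))
    if (length(waves) > 1L)
      for (w in waves[-1])
        x <- cbind(x, stats::setNames(
          data.frame(as.numeric(panel$wave == w)), paste0("wave_", w)))
    x <- as.matrix(x)
  }
  if (is.null(x) || is.null(y))
    stop("supply either a panel or x and y", call. = FALSE)
  if (!is.null(panel)) {
    dd <- drop_degenerate_columns(x)
    if (length(dd$dropped))
      warning("dropped degenerate column(s): ",
              paste(dd$dropped, collapse = ", "), call. = FALSE)
    x <- dd$x
  }
  check_design(x, y)
  fit <- stats::glm(y ~ x, family = stats::binomial())
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)",
         call. = FALSE)
  p_hat <- stats::fitted(fit)
  if (max(abs(y - p_hat)) < 1e-4) { # perfect classification
    beta <- stats::coef(fit)[-1]
    scaled <- abs(beta) * apply(x, 2, stats::sd)
    stop("perfect separation detected; offending column: ",
         colnames(x)[which.max(scaled)], call. = FALSE)
  }
  est <- summary(fit)$coefficients[-1, , drop = FALSE]
  rownames(est) <- colnames(x)
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    variable = colnames(x),
    or = exp(est[, "Estimate"]),
    ci_low = exp(est[, "Estimate"] - z * est[, "Std. Error"]),
    ci_high = exp(est[, "Estimate"] + z * est[, "Std. Error"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- list(table = tab, glm_fit = fit, n = length(y))
  class(res) <- "che_logistic"
  res
}

#' @export
print.che_logistic <- function(x, digits = 2, ...) {
  cat(sprintf("Pooled logistic regression (n = %d): odds ratios, Wald 95%% CI\n",
              x$n))
  out <- x$table
  out$or <- round(out$or, digits)
  out$ci_low <- round(out$ci_low, digits)
  out$ci_high <- round(out$ci_high, digits)
  print.data.frame(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.che_logistic <- function(object, ...)
  stats::setNames(object$table$or, object$table$variable)

pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

#' Quantile regression by pinball-loss minimisation
#'
#' Estimates the conditional tau-quantile of `y` given covariates by
#' minimising the asymmetric absolute (check / pinball) loss
#' sum rho_tau(y - X beta). The solver runs iteratively reweighted least
#' squares on a smoothed check loss, tightening the smoothing parameter, and
#' then polishes the exact-loss solution with a derivative-free local search;
#' convergence is to an objective tolerance of 1e-8. Confidence intervals
#' are by cluster bootstrap when `cluster` is supplied (resampling whole
#' households), otherwise by ordinary observation bootstrap.
#'
#' Used here as a robustness stage: household income is regressed on the CHE
#' flag and covariates at tau in {0.25, 0.5, 0.75}, so a negative CHE
#' coefficient at every quantile indicates that CHE households sit lower in
#' the income distribution throughout.
#'
#' @param x covariate matrix (no intercept column; one is added).
#' @param y numeric response.
#' @param tau quantile level in (0, 1).
#' @param n_boot bootstrap replicates for the 95% interval (0 to skip).
#' @param cluster optional cluster id (e.g. household) for the bootstrap.
#' @param seed seed for the bootstrap.
#' @return object of class `rq_pinball`: `coefficients` (with intercept),
#'   `tau`, `objective`, `ci` (matrix, if bootstrapped), `fitted`,
#'   `residuals`.
#' @export
#' @examples
#' x <- cbind(x = 1:20)
#' f <- fit_quantile(x, 1 + 2 * (1:20), tau = 0.5, n_boot = 0)
#' coef(f)  # (1, 2) exactly: noise-free line
fit_quantile <- function(x, y, tau = 0.5, n_boot = 200L, cluster = NULL,
                         seed = 1L) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must lie strictly between 0 and 1", call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y dimensions differ", call. = FALSE)
  if (nrow(x) <= ncol(x) + 1L)
    stop("need more observations than coefficients", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X))
    stop("degenerate design: collinear columns", call. = FALSE)

  beta <- rq_solve(X, y, tau)
  fitted <- drop(X %*% beta)
  obj <- pinball_loss(y - fitted, tau)

  ci <- NULL
  if (n_boot > 0L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(seed))
    if (is.null(cluster)) cluster <- seq_along(y)
    ids <- unique(cluster)
    idx_by <- split(seq_along(y), match(cluster, ids))
    B <- matrix(NA_real_, n_boot, ncol(X))
    for (b in seq_len(n_boot)) {
      pick <- sample.int(length(ids), length(ids), replace = TRUE)
      idx <- unlist(idx_by[pick], use.names = FALSE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank < ncol(Xb)) { B[b, ] <- NA; next }
      B[b, ] <- rq_solve(Xb, y[idx], tau, max_iter = 60L, polish = FALSE,
                         start = beta)
    }
    ci <- t(apply(B, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
    dimnames(ci) <- list(colnames(X), c("2.5 %", "97.5 %"))
  }

  res <- list(coefficients = stats::setNames(beta, colnames(X)),
              tau = tau, objective = obj, ci = ci,
              fitted = fitted, residuals = y - fitted, n = length(y))
  class(res) <- "rq_pinball"
  res
}

# IRLS on smoothed check loss with decreasing smoothing, then Nelder-Mead
# polish on the exact pinball objective; bootstrap replicates warm-start
# from the point estimate and skip the polish
rq_solve <- function(X, y, tau, max_iter = 200L, polish = TRUE,
                     start = NULL) {
  beta <- if (is.null(start)) stats::lm.fit(X, y)$coefficients else start
  beta[is.na(beta)] <- 0
  delta <- max(stats::sd(y), 1e-6) * 0.1
  obj_old <- Inf
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), delta)
    fit <- stats::lm.wfit(X, y, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- beta[is.na(beta_new)]
    obj <- pinball_loss(y - drop(X %*% beta_new), tau)
    if (is.finite(obj) && obj <= obj_old) beta <- beta_new
    if (abs(obj_old - obj) < 1e-10 * (1 + abs(obj))) {
      if (delta <= 1e-10) break
      delta <- delta / 10
    }
    obj_old <- min(obj_old, obj)
  }
  if (polish) {
    polished <- stats::optim(beta, function(b)
      pinball_loss(y - drop(X %*% b), tau),
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12))
    if (polished$value < pinball_loss(y - drop(X %*% beta), tau))
      beta <- polished$par
  }
  unname(beta)
}

#' @export
print.rq_pinball <- function(x, digits = 4, ...) {
  cat(sprintf("Quantile regression (tau = %.2f, n = %d, pinball loss %.4f)\n",
              x$tau, x$n, x$objective))
  if (is.null(x$ci)) print(round(x$coefficients, digits))
  else print(round(cbind(estimate = x$coefficients, x$ci), digits))
  invisible(x)
}

#' @export
coef.rq_pinball <- function(object, ...) object$coefficients

#' @export
residuals.rq_pinball <- function(object, ...) object$residuals

#' @export
predict.rq_pinball <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(1, as.matrix(newdata))
  drop(X %*% object$coefficients)
}

#' Quantile regression of household income on the CHE flag
#'
#' The robustness stage: regresses household income on the CHE flag plus the
#' standard determinants at the requested quantiles, with household-cluster
#' bootstrap intervals. A negative CHE coefficient that grows in magnitude
#' with tau mirrors a multiplicative income penalty for CHE households.
#'
#' @param panel a `che_panel` data frame.
#' @param config a [che_config()].
#' @param taus quantile levels.
#' @param n_boot bootstrap replicates per tau.
#' @param seed bootstrap seed.
#' @return named list of `rq_pinball` fits, one per tau.
#' @export
che_quantile_regression <- function(panel, config = che_config(),
                                    taus = c(0.25, 0.5, 0.75),
                                    n_boot = 200L, seed = 1L) {
  flag <- flag_che(panel, config)
  keep <- !is.na(flag)
  panel <- panel[keep, , drop = FALSE]
  che <- flag[keep]
  des <- che_design(panel)
  keep_cols <- setdiff(colnames(des$x),
                       c("econ_lower", "econ_middle", "econ_higher",
                         "econ_highest"))
  x <- cbind(che = che, time = as.numeric(factor(panel$wave)) - 1,
             des$x[, keep_cols, drop = FALSE])
  if (length(unique(panel$wave)) == 1L)
    x <- x[, colnames(x) != "time", drop = FALSE]
  dd <- drop_degenerate_columns(x)
  if (length(dd$dropped))
    warning("dropped degenerate column(s): ",
            paste(dd$dropped, collapse = ", "), call. = FALSE)
  x <- dd$x
  fits <- lapply(taus, function(tau)
    fit_quantile(x, panel$income, tau = tau, n_boot = n_boot,
                 cluster = panel$household_id, seed = seed))
  names(fits) <- paste0("q", taus * 100)
  fits
}
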