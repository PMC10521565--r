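#' Build the determinant design matrix for a household panel
#'
#' Assembles the covariate matrix used by the probit decomposition and the
#' pooled logistic regression: male, age-band dummies (reference: 50 years or
#' younger), no-spouse indicator (reference: living with a spouse), household
#' size, economic-status quintile dummies (household income quintiles within
#' the analysed sample; reference: lowest), junior-high-plus education,
#' insurance, smoking, drinking, disability, chronic disease, outpatient and
#' inpatient indicators and visit counts.
#'
#' @param panel a `che_panel` data frame (typically one wave).
#' @return list with `x` (numeric matrix), `families` (named list grouping
#'   dummy columns into declared families), and `econ_quintile` (the
#'   quintile factor).
#' @export
che_design <- function(panel) {
  q <- stats::quantile(panel$income, probs = seq(0.2, 0.8, by = 0.2),
                       type = 7, names = FALSE)
  econ <- cut(panel$income, breaks = c(-Inf, q, Inf),
              labels = c("lowest", "lower", "middle", "higher", "highest"))
  x <- cbind(
    male = panel$male,
    age_51_60 = as.numeric(panel$age_band == "b51_60"),
    age_61_70 = as.numeric(panel$age_band == "b61_70"),
    age_ge71 = as.numeric(panel$age_band == "ge71"),
    no_spouse = 1 - panel$spouse,
    hh_size = panel$hh_size,
    econ_lower = as.numeric(econ == "lower"),
    econ_middle = as.numeric(econ == "middle"),
    econ_higher = as.numeric(econ == "higher"),
    econ_highest = as.numeric(econ == "highest"),
    edu_junior_plus = panel$edu_junior_plus,
    insured = panel$insured,
    smoke = panel$smoke,
    drink = panel$drink,
    disability = panel$disability,
    chronic = panel$chronic,
    outpatient = panel$outpatient,
    outpatient_times = panel$outpatient_times,
    inpatient = panel$inpatient,
    inpatient_times = panel$inpatient_times
  )
  families <- list(
    economic_status = c("econ_lower", "econ_middle", "econ_higher",
                        "econ_highest"),
    age = c("age_51_60", "age_61_70", "age_ge71")
  )
  list(x = x, families = families, econ_quintile = econ)
}

drop_degenerate_columns <- function(x) {
  keep <- apply(x, 2, function(col) length(unique(col)) > 1L)
  dropped <- colnames(x)[!keep]
  x <- x[, keep, drop = FALSE]
  # greedily drop trailing columns that are exact linear combinations of
  # earlier ones (e.g. visit counts equal to the use indicator in small
  # samples)
  qx <- qr(cbind(1, x))
  while (qx$rank < ncol(x) + 1L) {
    j <- max(qx$pivot[seq_len(ncol(x) + 1L) > qx$rank]) - 1L
    dropped <- c(dropped, colnames(x)[j])
    x <- x[, -j, drop = FALSE]
    qx <- qr(cbind(1, x))
  }
  list(x = x, dropped = dropped)
}

check_design <- function(x, y) {
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; probit/logistic fit undefined",
         call. = FALSE)
  const <- colnames(x)[apply(x, 2, function(col) length(unique(col)) == 1L)]
  if (length(const))
    stop("constant column(s) in design: ", paste(const, collapse = ", "),
         call. = FALSE)
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1L)
    stop("design matrix is rank deficient (exact collinearity)",
         call. = FALSE)
  invisible(TRUE)
}

#' Probit model with average marginal effects
#'
#' Maximum-likelihood probit fit of a binary outcome on a covariate matrix,
#' reporting latent-scale coefficients, marginal effects dP/dx_j, residuals
#' y_i - Phi(x_i beta) and the log-likelihood. Marginal effects are average
#' marginal effects by default (the sample mean of phi(x_i beta) times the
#' coefficient); `me_type = "at_means"` evaluates the density at the
#' covariate means instead.
#'
#' @param x numeric covariate matrix with named columns (no intercept
#'   column; one is added).
#' @param y binary 0/1 outcome vector.
#' @param me_type `"average"` (default) or `"at_means"`.
#' @return object of class `probit_fit`: list with `coefficients`,
#'   `marginal_effects`, `residuals`, `fitted`, `log_likelihood`,
#'   `converged`, `me_type`, and the underlying `glm` object.
#' @export
fit_probit <- function(x, y, me_type = c("average", "at_means")) {
  me_type <- match.arg(me_type)
  x <- as.matrix(x)
  check_design(x, y)
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                        family = stats::binomial(link = "probit"),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  if (!fit$converged)
    stop("probit fit did not converge (possible separation); ",
         "largest-coefficient column: ",
         names(which.max(abs(fit$coefficients[-1]))), call. = FALSE)
  beta <- fit$coefficients
  eta <- drop(cbind(1, x) %*% beta)
  p_hat <- stats::pnorm(eta)
  if (max(abs(y - p_hat)) < 1e-4) { # perfect classification
    scaled <- abs(beta[-1]) * apply(x, 2, stats::sd)
    stop("perfect separation detected; offending column: ",
         names(which.max(scaled)), call. = FALSE)
  }
  dens_factor <- if (me_type == "average") mean(stats::dnorm(eta))
                 else stats::dnorm(sum(beta * c(1, colMeans(x))))
  me <- dens_factor * beta[-1]
  p_safe <- pmin(pmax(p_hat, 1e-15), 1 - 1e-15)
  ll <- sum(y * log(p_safe) + (1 - y) * log(1 - p_safe))
  res <- list(coefficients = beta, marginal_effects = me,
              residuals = y - p_hat, fitted = p_hat,
              log_likelihood = ll, converged = fit$converged,
              me_type = me_type, x = x, y = y, glm_fit = fit)
  class(res) <- "probit_fit"
  res
}

#' @export
print.probit_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Probit fit: n = %d, logLik = %.2f (%s marginal effects)\n",
              length(x$y), x$log_likelihood, x$me_type))
  print(round(cbind(coef = x$coefficients[-1],
                    dP.dx = x$marginal_effects), digits))
  invisible(x)
}

#' @export
coef.probit_fit <- function(object, ...) object$coefficients

#' @export
residuals.probit_fit <- function(object, ...) object$residuals

#' Decompose the concentration index into determinant contributions
#'
#' Wagstaff-style decomposition of the concentration index of a binary
#' outcome: a probit model links the outcome to its determinants; each
#' determinant's contribution is its elasticity (marginal effect times the
#' covariate mean, over the outcome mean) times the covariate's own
#' concentration index against the shared income ranks. The residual is the
#' total index minus the summed contributions, so the decomposition identity
#' C = sum(contributions) + residual holds to machine precision by
#' construction. Percent contributions are reported both raw
#' (contribution / C * 100) and rescaled to exclude the residual.
#'
#' @param panel a `che_panel` data frame (typically one wave); alternatively
#'   supply `x`, `y` and `income` directly.
#' @param config a [che_config()] used to flag the outcome when `panel` is
#'   given.
#' @param x,y,income optional explicit design matrix, 0/1 outcome and income
#'   vector, bypassing [che_design()].
#' @param weights optional positive weights.
#' @param families named list of dummy families for group totals; defaults
#'   to the [che_design()] families when `panel` is given.
#' @param me_type marginal-effect type, see [fit_probit()].
#' @param rank_mode rank convention, see [fractional_rank()].
#' @return object of class `cindex_decomp`: `rows` (per-determinant data
#'   frame with mean, marginal effect, elasticity, covariate concentration
#'   index, contribution, percent, percent_excl_residual), `group_totals`,
#'   `total` (the outcome's concentration index), `residual`,
#'   `residual_percent`, `mu`, `n`, `probit`.
#' @export
#' @examples
#' panel <- generate_panel(panel_config(n_households = 400, seed = 3))
#' d <- decompose_cindex(panel[panel$wave == 2013, ])
#' d$total - (sum(d$rows$contribution) + d$residual)  # 0 by construction
decompose_cindex <- function(panel = NULL, config = che_config(),
                             x = NULL, y = NULL, income = NULL,
                             weights = NULL, families = NULL,
                             me_type = c("average", "at_means"),
                             rank_mode = c("midpoint", "order")) {
  me_type <- match.arg(me_type)
  rank_mode <- match.arg(rank_mode)
  if (!is.null(panel)) {
    flag <- flag_che(panel, config)
    keep <- !is.na(flag)
    panel <- panel[keep, , drop = FALSE]
    y <- flag[keep]
    des <- che_design(panel)
    x <- des$x
    if (is.null(families)) families <- des$families
    income <- panel$income
  }
  if (is.null(x) || is.null(y) || is.null(income))
    stop("supply either a panel or x, y and income", call. = FALSE)
  x <- as.matrix(x)
  dd <- drop_degenerate_columns(x)
  x <- dd$x
  if (length(dd$dropped))
    warning("dropped constant column(s): ",
            paste(dd$dropped, collapse = ", "), call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(y))

  rank <- fractional_rank(income, weights, mode = rank_mode)
  total <- concentration_index(y, rank = rank, weights = weights,
                               se_method = "none")
  mu <- total$mu

  fit <- fit_probit(x, y, me_type = me_type)
  me <- fit$marginal_effects

  xbar <- colMeans(x)
  elasticity <- me * xbar / mu
  cj <- vapply(colnames(x), function(j) {
    concentration_index(x[, j], rank = rank, weights = weights,
                        se_method = "none")$index
  }, numeric(1))
  contribution <- elasticity * cj
  percent <- contribution / total$index * 100
  residual <- total$index - sum(contribution)
  residual_percent <- residual / total$index * 100
  percent_excl <- contribution / sum(contribution) * 100

  rows <- data.frame(
    variable = colnames(x), mean = xbar, marginal_effect = me,
    elasticity = elasticity, cindex = cj, contribution = contribution,
    percent = percent, percent_excl_residual = percent_excl,
    row.names = NULL, stringsAsFactors = FALSE
  )

  group_totals <- NULL
  if (!is.null(families))
    group_totals <- group_contributions(
      stats::setNames(rows$percent, rows$variable), families)

  res <- list(rows = rows, group_totals = group_totals,
              total = total$index, residual = residual,
              residual_percent = residual_percent,
              mu = mu, n = length(y), families = families,
              probit = fit, rank = rank)
  class(res) <- "cindex_decomp"
  res
}

#' @export
print.cindex_decomp <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Decomposition of the concentration index (C = %.*f, mean outcome %.*f, n = %d)\n",
    digits, x$total, digits, x$mu, x$n))
  out <- x$rows[, c("variable", "contribution", "percent")]
  out$contribution <- round(out$contribution, digits)
  out$percent <- round(out$percent, 2)
  print.data.frame(out, row.names = FALSE)
  cat(sprintf("residual: %.*f (%.2f%%)\n", digits, x$residual,
              x$residual_percent))
  if (!is.null(x$group_totals)) {
    cat("group totals (% of C):\n")
    print(round(x$group_totals, 2))
  }
  invisible(x)
}

#' @export
summary.cindex_decomp <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.cindex_decomp <- function(object, ...)
  stats::setNames(object$rows$contribution, object$rows$variable)

#' Sum contributions over declared dummy families
#'
#' Aggregates per-dummy percent (or contribution) values into family totals,
#' e.g. the four economic-status dummies or the three age-band dummies. The
#' input is either a `cindex_decomp` result (its percent column is used) or
#' a named numeric vector, such as a published table column being checked
#' for internal consistency.
#'
#' @param x a `cindex_decomp` or a named numeric vector.
#' @param families named list mapping family name to member variable names.
#' @return named numeric vector of family totals.
#' @export
#' @examples
#' group_contributions(c(a = 1.5, b = 2.5, c = -1), list(ab = c("a", "b")))
group_contributions <- function(x, families) {
  if (inherits(x, "cindex_decomp"))
    x <- stats::setNames(x$rows$percent, x$rows$variable)
  if (is.null(names(x)))
    stop("values must be named", call. = FALSE)
  vapply(names(families), function(fam) {
    members <- families[[fam]]
    missing <- setdiff(members, names(x))
    if (length(missing))
      stop("unknown member(s) in family '", fam, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    sum(x[members])
  }, numeric(1))
}
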