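#' Configuration for the synthetic household-panel generator
#'
#' Builds and validates the full set of distributional knobs used by
#' [generate_panel()]. The defaults emulate a balanced three-wave rural
#' household survey: log-normal household income, capacity to pay (CTP) as a
#' clamped non-food share of income, and out-of-pocket (OOP) health spending
#' that is zero with probability `1 - oop_base_rate` and otherwise a
#' gamma-distributed share of CTP, log-shifted by an income gradient and by
#' head-of-household covariate effects. Covariate marginal prevalences default
#' to the baseline characteristics of the emulated survey (e.g. 48.85% male
#' heads, 66.52% with chronic disease, 96.23% insured).
#'
#' A negative `income_gradient` makes poorer households spend a larger share
#' of their capacity to pay, inducing pro-poor (negative) income-related
#' inequality in catastrophic health expenditure downstream; a gradient of
#' zero with all covariate effects zero makes the OOP share independent of
#' income rank, so the concentration index of CHE is zero in expectation.
#'
#' @param n_households number of households (>= 2).
#' @param n_waves number of survey waves; default 3.
#' @param waves wave labels, length `n_waves`; default 2013/2015/2018.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   panel.
#' @param income_log_mean,income_log_sd parameters of the log-normal household
#'   income distribution (log currency units per year).
#' @param income_wave_rho across-wave correlation of log income in (0, 1).
#' @param nonfood_share_mean,nonfood_share_sd mean and sd of the non-food
#'   expenditure share of income, clamped to (0.05, 0.95).
#' @param oop_base_rate probability that a household has any health spending
#'   in a wave.
#' @param oop_gamma_shape,oop_gamma_scale gamma parameters of the positive
#'   OOP-to-CTP share.
#' @param income_gradient coefficient linking centred log income to the log
#'   OOP share; negative implies pro-poor CHE inequality.
#' @param covariate_prevalences named vector/list of marginal probabilities
#'   for the 0/1 head-of-household covariates.
#' @param age_band_probs named probabilities of the four age bands
#'   (`le50`, `b51_60`, `b61_70`, `ge71`); must sum to 1.
#' @param covariate_effects named log-scale effects on the OOP share; names
#'   must be 0/1 covariates or age-band dummies (`age_51_60`, `age_61_70`,
#'   `age_ge71`).
#' @param hh_size_lambda Poisson rate of household size minus one.
#' @param outpatient_extra_lambda,inpatient_extra_lambda Poisson rates of
#'   visit counts beyond the first, among users.
#'
#' @return An object of class `panel_config` (a validated list).
#' @seealso [generate_panel()], [expected_marginals()]
#' @export
#' @examples
#' cfg <- panel_config(n_households = 200, seed = 1)
#' cfg$covariate_prevalences[["chronic"]]
panel_config <- function(n_households = 2575,
                         n_waves = 3,
                         waves = NULL,
                         seed = 1L,
                         income_log_mean = 9.5,
                         income_log_sd = 0.8,
                         income_wave_rho = 0.9,
                         nonfood_share_mean = 0.55,
                         nonfood_share_sd = 0.15,
                         oop_base_rate = 0.85,
                         oop_gamma_shape = 1.1,
                         oop_gamma_scale = 0.11,
                         income_gradient = -0.25,
                         covariate_prevalences = NULL,
                         age_band_probs = NULL,
                         covariate_effects = NULL,
                         hh_size_lambda = 0.69,
                         outpatient_extra_lambda = 0.52,
                         inpatient_extra_lambda = 0.05) {
  defaults_prev <- c(
    male = 0.4885, spouse = 0.8769, edu_junior_plus = 0.2757,
    insured = 0.9623, smoke = 0.6159, drink = 0.4866,
    disability = 0.0691, chronic = 0.6652,
    outpatient = 0.2959, inpatient = 0.1068
  )
  defaults_age <- c(le50 = 0.0183, b51_60 = 0.3243,
                    b61_70 = 0.4062, ge71 = 0.2513)
  defaults_eff <- c(
    age_51_60 = 0.25, age_61_70 = 0.55, age_ge71 = 0.85,
    chronic = 0.35, disability = 0.20, outpatient = 0.30, inpatient = 0.60
  )

  prev <- defaults_prev
  if (!is.null(covariate_prevalences)) {
    covariate_prevalences <- unlist(covariate_prevalences)
    unknown <- setdiff(names(covariate_prevalences), names(defaults_prev))
    if (length(unknown))
      stop("covariate_prevalences: unknown covariate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    prev[names(covariate_prevalences)] <- covariate_prevalences
  }
  age <- defaults_age
  if (!is.null(age_band_probs)) {
    age_band_probs <- unlist(age_band_probs)
    unknown <- setdiff(names(age_band_probs), names(defaults_age))
    if (length(unknown))
      stop("age_band_probs: unknown band(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    age[names(age_band_probs)] <- age_band_probs
  }
  eff <- defaults_eff
  if (!is.null(covariate_effects)) {
    covariate_effects <- unlist(covariate_effects)
    allowed <- c(names(defaults_prev),
                 c("age_51_60", "age_61_70", "age_ge71"))
    unknown <- setdiff(names(covariate_effects), allowed)
    if (length(unknown))
      stop("covariate_effects: unknown covariate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    eff <- covariate_effects
  }

  if (is.null(waves)) {
    waves <- if (n_waves == 3) c(2013L, 2015L, 2018L)
             else seq_len(n_waves)
  }

  # published survey-table percentages can sum to 100.01 after rounding;
  # renormalise so sampling probabilities are exact
  age <- age / sum(age)

  cfg <- list(
    n_households = n_households, n_waves = n_waves, waves = waves,
    seed = seed,
    income_log_mean = income_log_mean, income_log_sd = income_log_sd,
    income_wave_rho = income_wave_rho,
    nonfood_share_mean = nonfood_share_mean,
    nonfood_share_sd = nonfood_share_sd,
    oop_base_rate = oop_base_rate,
    oop_gamma_shape = oop_gamma_shape, oop_gamma_scale = oop_gamma_scale,
    income_gradient = income_gradient,
    covariate_prevalences = prev,
    age_band_probs = age,
    covariate_effects = eff,
    hh_size_lambda = hh_size_lambda,
    outpatient_extra_lambda = outpatient_extra_lambda,
    inpatient_extra_lambda = inpatient_extra_lambda
  )
  class(cfg) <- "panel_config"
  validate_panel_config(cfg)
  cfg
}

validate_panel_config <- function(cfg) {
  chk_pos_int <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x < min || x != round(x))
      stop("invalid config field '", name, "': must be an integer >= ",
           min, call. = FALSE)
  }
  chk_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stop("invalid config field '", name, "': must be > 0", call. = FALSE)
  }
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("invalid config field '", name, "': probabilities must lie in [0,1]",
           call. = FALSE)
  }
  chk_pos_int(cfg$n_households, "n_households", min = 2L)
  chk_pos_int(cfg$n_waves, "n_waves", min = 1L)
  if (length(cfg$waves) != cfg$n_waves)
    stop("invalid config field 'waves': length must equal n_waves",
         call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("invalid config field 'seed': must be a single integer",
         call. = FALSE)
  chk_pos(cfg$income_log_sd, "income_log_sd")
  chk_prob(cfg$income_wave_rho, "income_wave_rho")
  chk_pos(cfg$nonfood_share_sd, "nonfood_share_sd")
  chk_prob(cfg$nonfood_share_mean, "nonfood_share_mean")
  chk_prob(cfg$oop_base_rate, "oop_base_rate")
  chk_pos(cfg$oop_gamma_shape, "oop_gamma_shape")
  chk_pos(cfg$oop_gamma_scale, "oop_gamma_scale")
  if (!is.numeric(cfg$income_gradient) || length(cfg$income_gradient) != 1L)
    stop("invalid config field 'income_gradient': must be a single number",
         call. = FALSE)
  chk_prob(cfg$covariate_prevalences, "covariate_prevalences")
  chk_prob(cfg$age_band_probs, "age_band_probs")
  if (abs(sum(cfg$age_band_probs) - 1) > 0.01)
    stop("invalid config field 'age_band_probs': must sum to 1",
         call. = FALSE)
  chk_pos(cfg$hh_size_lambda, "hh_size_lambda")
  invisible(cfg)
}

#' @export
print.panel_config <- function(x, ...) {
  cat("Synthetic household-panel configuration\n")
  cat(sprintf("  %d households x %d waves (%s), seed %d\n",
              x$n_households, x$n_waves,
              paste(x$waves, collapse = "/"), as.integer(x$seed)))
  cat(sprintf("  log-income ~ N(%.2f, %.2f); non-food share ~ N(%.2f, %.2f)\n",
              x$income_log_mean, x$income_log_sd,
              x$nonfood_share_mean, x$nonfood_share_sd))
  cat(sprintf("  OOP: base rate %.2f, share ~ Gamma(%.2f, scale %.2f), income gradient %.2f\n",
              x$oop_base_rate, x$oop_gamma_shape, x$oop_gamma_scale,
              x$income_gradient))
  invisible(x)
}

#' Expected covariate marginals of a generator configuration
#'
#' Returns the configured marginal prevalence of every 0/1 covariate and age
#' band. Generated panels match these within binomial sampling error.
#'
#' @param config a [panel_config()] object.
#' @return named numeric vector of expected prevalences.
#' @export
#' @examples
#' expected_marginals(panel_config(n_households = 100))[["chronic"]]
expected_marginals <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  c(config$covariate_prevalences,
    stats::setNames(config$age_band_probs,
                    paste0("age_", names(config$age_band_probs))))
}
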