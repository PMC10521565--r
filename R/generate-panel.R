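#' Generate a balanced synthetic household panel
#'
#' Draws a balanced panel of `n_households x n_waves` household-wave records
#' with the statistical structure the downstream inequality analysis assumes:
#' right-skewed (log-normal) household income with across-wave persistence,
#' capacity to pay as a clamped non-food share of income, and out-of-pocket
#' (OOP) health spending that is zero with probability `1 - oop_base_rate`
#' and otherwise a gamma share of capacity to pay, shifted on the log scale
#' by `income_gradient * (log income - income_log_mean)` plus covariate
#' effects.
#'
#' Head-of-household characteristics (sex, age band, marital status,
#' education, insurance, smoking, drinking, disability, chronic disease,
#' household size) are drawn once per household; healthcare utilisation
#' (outpatient/inpatient indicators and visit counts) and income are drawn
#' per wave. Age in years is uniform within the baseline band and increments
#' with the wave calendar gap, so a 65-year cutoff can be applied per wave.
#' One pseudo-random stream is used per panel, seeded once from
#' `config$seed`.
#'
#' @param config a validated [panel_config()].
#' @return A `data.frame` of class `che_panel`, one row per household-wave,
#'   with columns `household_id`, `wave`, `income`, `food_exp`,
#'   `nonfood_exp`, `oop`, `male`, `age_band`, `age_years`, `spouse`,
#'   `hh_size`, `edu_junior_plus`, `insured`, `smoke`, `drink`,
#'   `disability`, `chronic`, `outpatient`, `outpatient_times`,
#'   `inpatient`, `inpatient_times`.
#' @export
#' @examples
#' panel <- generate_panel(panel_config(n_households = 50, seed = 7))
#' nrow(panel)  # 150 = 50 households x 3 waves
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  validate_panel_config(config)

  n <- config$n_households
  waves <- config$waves
  nw <- config$n_waves

  # private RNG stream: whole-panel reproducibility without touching the
  # caller's .Random.seed
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(config$seed))

  prev <- config$covariate_prevalences
  draw <- function(name) stats::rbinom(n, 1L, prev[[name]])

  male <- draw("male"); spouse <- draw("spouse")
  edu <- draw("edu_junior_plus"); insured <- draw("insured")
  smoke <- draw("smoke"); drink <- draw("drink")
  disability <- draw("disability"); chronic <- draw("chronic")
  hh_size <- 1L + stats::rpois(n, config$hh_size_lambda)

  band_names <- c("le50", "b51_60", "b61_70", "ge71")
  band <- sample(band_names, n, replace = TRUE,
                 prob = config$age_band_probs[band_names])
  age0 <- numeric(n)
  age0[band == "le50"]   <- stats::runif(sum(band == "le50"),   45, 50)
  age0[band == "b51_60"] <- stats::runif(sum(band == "b51_60"), 51, 60)
  age0[band == "b61_70"] <- stats::runif(sum(band == "b61_70"), 61, 70)
  age0[band == "ge71"]   <- stats::runif(sum(band == "ge71"),   71, 85)

  eff <- config$covariate_effects
  eff_of <- function(name, x) if (name %in% names(eff)) eff[[name]] * x else 0
  # time-invariant part of the log OOP-share shift
  base_shift <-
    eff_of("male", male) + eff_of("spouse", spouse) +
    eff_of("edu_junior_plus", edu) + eff_of("insured", insured) +
    eff_of("smoke", smoke) + eff_of("drink", drink) +
    eff_of("disability", disability) + eff_of("chronic", chronic) +
    eff_of("age_51_60", as.numeric(band == "b51_60")) +
    eff_of("age_61_70", as.numeric(band == "b61_70")) +
    eff_of("age_ge71", as.numeric(band == "ge71"))

  rho <- config$income_wave_rho
  z_house <- stats::rnorm(n)

  wave_num <- suppressWarnings(as.numeric(waves))
  wave_gap <- if (anyNA(wave_num)) seq_len(nw) - 1
              else wave_num - wave_num[1]

  out <- vector("list", nw)
  for (w in seq_len(nw)) {
    z <- rho * z_house + sqrt(1 - rho^2) * stats::rnorm(n)
    log_inc <- config$income_log_mean + config$income_log_sd * z
    income <- exp(log_inc)
    share <- pmin(pmax(
      stats::rnorm(n, config$nonfood_share_mean, config$nonfood_share_sd),
      0.05), 0.95)
    nonfood <- share * income
    food <- (1 - share) * income

    outpatient <- draw("outpatient")
    inpatient <- draw("inpatient")
    outpatient_times <- outpatient *
      (1L + stats::rpois(n, config$outpatient_extra_lambda))
    inpatient_times <- inpatient *
      (1L + stats::rpois(n, config$inpatient_extra_lambda))

    shift <- base_shift +
      eff_of("outpatient", outpatient) + eff_of("inpatient", inpatient) +
      config$income_gradient * (log_inc - config$income_log_mean)
    any_oop <- stats::rbinom(n, 1L, config$oop_base_rate)
    oop_share <- stats::rgamma(n, config$oop_gamma_shape,
                               scale = config$oop_gamma_scale) * exp(shift)
    oop <- any_oop * oop_share * nonfood

    out[[w]] <- data.frame(
      household_id = seq_len(n),
      wave = waves[w],
      income = income, food_exp = food, nonfood_exp = nonfood, oop = oop,
      male = male, age_band = band, age_years = age0 + wave_gap[w],
      spouse = spouse, hh_size = hh_size, edu_junior_plus = edu,
      insured = insured, smoke = smoke, drink = drink,
      disability = disability, chronic = chronic,
      outpatient = outpatient, outpatient_times = outpatient_times,
      inpatient = inpatient, inpatient_times = inpatient_times,
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  class(panel) <- c("che_panel", "data.frame")
  attr(panel, "balanced") <- TRUE
  panel
}

panel_columns <- c(
  "household_id", "wave", "income", "food_exp", "nonfood_exp", "oop",
  "male", "age_band", "age_years", "spouse", "hh_size", "edu_junior_plus",
  "insured", "smoke", "drink", "disability", "chronic",
  "outpatient", "outpatient_times", "inpatient", "inpatient_times"
)

#' Write / read a household panel as delimited text
#'
#' Plain CSV with a header row of canonical column names; `read_panel`
#' validates the schema and numeric fields so a write-then-read round trip
#' reproduces the panel to full precision.
#'
#' @param panel a `che_panel` data frame (or any data frame with the
#'   canonical columns).
#' @param path file path.
#' @return `read_panel` returns a `che_panel` data frame.
#' @export
write_panel <- function(panel, path) {
  missing_cols <- setdiff(panel_columns, names(panel))
  if (length(missing_cols))
    stop("panel is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(panel[, panel_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(panel_columns, names(df))
  if (length(missing_cols))
    stop("panel file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  numeric_cols <- setdiff(panel_columns, c("wave", "age_band"))
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data row ",
             bad[1], ": '", v[bad[1]], "'", call. = FALSE)
      df[[col]] <- parsed
    }
  }
  df <- df[, panel_columns]
  class(df) <- c("che_panel", "data.frame")
  df
}
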