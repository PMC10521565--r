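#' Catastrophic health expenditure (CHE) configuration
#'
#' @param threshold CHE threshold as a fraction of capacity to pay, strictly
#'   between 0 and 1; default 0.40. A household is flagged when its
#'   out-of-pocket share of capacity to pay is greater than or equal to the
#'   threshold (boundary inclusive).
#' @param ctp_definition base of the ratio; currently only `"nonfood"`
#'   (capacity to pay = household non-food expenditure).
#' @param ci_method confidence-interval method for incidence: `"normal"`
#'   (default, p +/- 1.96 sqrt(p(1-p)/n), clamped to `[0,1]`) or `"wilson"`.
#' @return a list of class `che_config`.
#' @export
che_config <- function(threshold = 0.40, ctp_definition = c("nonfood"),
                       ci_method = c("normal", "wilson")) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly between 0 and 1", call. = FALSE)
  cfg <- list(threshold = threshold,
              ctp_definition = match.arg(ctp_definition),
              ci_method = match.arg(ci_method))
  class(cfg) <- "che_config"
  cfg
}

#' Capacity to pay of each household record
#'
#' Under the default definition, capacity to pay (CTP) is household non-food
#' expenditure. Records with CTP <= 0 have an undefined OOP/CTP ratio and are
#' reported as excluded rather than raising an error.
#'
#' @param panel a data frame with at least `nonfood_exp`.
#' @param config a [che_config()].
#' @return numeric vector of CTP values; `NA` for excluded (CTP <= 0)
#'   records, with the number of exclusions in attribute `"n_excluded"`.
#' @export
compute_ctp <- function(panel, config = che_config()) {
  ctp <- switch(config$ctp_definition, nonfood = panel$nonfood_exp)
  excluded <- !is.finite(ctp) | ctp <= 0
  ctp[excluded] <- NA_real_
  attr(ctp, "n_excluded") <- sum(excluded)
  ctp
}

#' Flag catastrophic health expenditure
#'
#' A record incurs CHE when out-of-pocket health spending is at least
#' `threshold` (default 40%) of capacity to pay; the boundary is inclusive.
#'
#' @param panel data frame with `oop` and `nonfood_exp` columns, or a
#'   numeric vector of OOP amounts if `ctp` is supplied.
#' @param config a [che_config()].
#' @param ctp optional numeric vector of capacity to pay, overriding
#'   [compute_ctp()].
#' @return integer 0/1 vector; `NA` where CTP is excluded.
#' @export
#' @examples
#' flag_che(data.frame(oop = c(4000, 0, 5000), nonfood_exp = 10000))
flag_che <- function(panel, config = che_config(), ctp = NULL) {
  if (is.data.frame(panel)) {
    oop <- panel$oop
    if (is.null(ctp)) ctp <- compute_ctp(panel, config)
  } else {
    oop <- panel
    if (is.null(ctp)) stop("ctp must be supplied when panel is a vector",
                           call. = FALSE)
  }
  if (length(oop) != length(ctp))
    stop("oop and ctp lengths differ", call. = FALSE)
  if (any(oop < 0, na.rm = TRUE))
    stop("negative out-of-pocket spending", call. = FALSE)
  flag <- ifelse(is.na(ctp), NA_integer_,
                 as.integer(oop / ctp >= config$threshold))
  flag
}

#' Per-wave CHE incidence with confidence intervals
#'
#' Incidence is the share of includable households flagged as incurring CHE
#' in a wave, with a 95% interval by normal approximation (or Wilson, per
#' config), clamped to `[0, 1]`.
#'
#' @param panel a `che_panel` data frame.
#' @param config a [che_config()].
#' @param waves waves to report; default all waves present.
#' @return data frame of class `che_incidence` with columns `wave`, `n`,
#'   `n_che`, `n_excluded`, `incidence`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' panel <- generate_panel(panel_config(n_households = 300, seed = 2))
#' che_incidence(panel)
che_incidence <- function(panel, config = che_config(), waves = NULL) {
  if (is.null(waves)) waves <- unique(panel$wave)
  rows <- lapply(waves, function(w) {
    sub <- panel[panel$wave == w, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no records in wave '", w, "'", call. = FALSE)
    flag <- flag_che(sub, config)
    n_excluded <- sum(is.na(flag))
    flag <- flag[!is.na(flag)]
    n <- length(flag)
    if (n == 0L)
      stop("no includable records in wave '", w, "'", call. = FALSE)
    n_che <- sum(flag)
    ci <- incidence_ci(n_che, n, config$ci_method)
    data.frame(wave = w, n = n, n_che = n_che, n_excluded = n_excluded,
               incidence = n_che / n, ci_low = ci[1], ci_high = ci[2])
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("che_incidence", "data.frame")
  res
}

incidence_ci <- function(n_che, n, method = "normal", level = 0.95) {
  p <- n_che / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "normal") {
    half <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(max(0, centre - half), min(1, centre + half))
  }
}

#' @export
print.che_incidence <- function(x, digits = 4, ...) {
  cat("CHE incidence by wave\n")
  y <- x
  y$incidence <- round(y$incidence, digits)
  y$ci_low <- round(y$ci_low, digits)
  y$ci_high <- round(y$ci_high, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
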