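#' Configuration of a full analysis run
#'
#' Bundles every setting of the end-to-end pipeline: the input (a panel file
#' path or a generator configuration), the CHE definition, the rank
#' convention, the uncertainty method for the concentration index, the
#' heterogeneity strata and the bootstrap seed. Validated up front so a run
#' fails before any stage executes.
#'
#' @param input a [panel_config()] to generate from, or a path to a panel
#'   CSV readable by [read_panel()].
#' @param che a [che_config()].
#' @param rank_mode rank convention, see [fractional_rank()].
#' @param se_method `"regression"` (analytic) or `"bootstrap"` for the
#'   concentration-index intervals.
#' @param n_boot bootstrap replicates when any bootstrap method is used.
#' @param seed seed for all stochastic stages (mandatory when
#'   `se_method = "bootstrap"` or quantile bootstrap is on).
#' @param strata character subset of `c("age65", "chronic", "education")`:
#'   the supported heterogeneity splits (head aged >= 65 vs < 65; chronic
#'   disease yes/no; junior-high-plus vs elementary-or-below education).
#' @param quantile_taus quantile levels for the robustness regression.
#' @param quantile_boot bootstrap replicates per quantile fit (0 to skip
#'   intervals).
#' @return a list of class `run_config`.
#' @export
run_config <- function(input = panel_config(),
                       che = che_config(),
                       rank_mode = c("midpoint", "order"),
                       se_method = c("regression", "bootstrap"),
                       n_boot = 500L,
                       seed = 1L,
                       strata = c("age65", "chronic", "education"),
                       quantile_taus = c(0.25, 0.5, 0.75),
                       quantile_boot = 200L) {
  rank_mode <- match.arg(rank_mode)
  se_method <- match.arg(se_method)
  if (!(inherits(input, "panel_config") ||
        (is.character(input) && length(input) == 1L)))
    stop("input must be a panel_config or a file path", call. = FALSE)
  if (!inherits(che, "che_config"))
    stop("che must be a che_config", call. = FALSE)
  unknown <- setdiff(strata, c("age65", "chronic", "education"))
  if (length(unknown))
    stop("unknown stratum (strata must be among age65, chronic, education): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(seed) || is.na(seed))
    stop("seed is mandatory", call. = FALSE)
  cfg <- list(input = input, che = che, rank_mode = rank_mode,
              se_method = se_method, n_boot = as.integer(n_boot),
              seed = as.integer(seed), strata = strata,
              quantile_taus = quantile_taus,
              quantile_boot = as.integer(quantile_boot))
  class(cfg) <- "run_config"
  cfg
}

stratum_predicates <- function(name) {
  switch(name,
    age65 = list(
      "age_ge65" = function(p) p$age_years >= 65,
      "age_lt65" = function(p) p$age_years < 65),
    chronic = list(
      "chronic_yes" = function(p) p$chronic == 1,
      "chronic_no" = function(p) p$chronic == 0),
    education = list(
      "edu_junior_plus" = function(p) p$edu_junior_plus == 1,
      "edu_elementary_below" = function(p) p$edu_junior_plus == 0),
    stop("unknown stratum: ", name, call. = FALSE))
}

#' Run the full CHE inequality pipeline
#'
#' Executes, from one configuration: CHE flagging and per-wave incidence;
#' per-wave concentration index and curve; probit decomposition of the index
#' per wave; heterogeneity strata (index and decomposition per stratum, with
#' ranks recomputed within each stratum); pooled logistic odds ratios; and
#' quantile-regression robustness. All stochastic stages derive from
#' `config$seed`, so a rerun with the same configuration is identical.
#'
#' @param config a [run_config()].
#' @return a list of class `che_run` with elements `panel`, `incidence`,
#'   `cindex` (per-wave data frame), `curves`, `decomposition` (per wave),
#'   `strata`, `logistic`, `quantile`, and `log` (exclusion counts, seeds,
#'   settings).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  panel <- if (inherits(config$input, "panel_config"))
    generate_panel(config$input) else read_panel(config$input)
  waves <- sort(unique(panel$wave))

  flag_all <- flag_che(panel, config$che)
  n_excluded <- sum(is.na(flag_all))

  incidence <- che_incidence(panel, config$che, waves = waves)

  cindex_rows <- list()
  curves <- list()
  decomp <- list()
  errors <- list()
  for (w in waves) {
    sub <- panel[panel$wave == w, , drop = FALSE]
    flag <- flag_che(sub, config$che)
    keep <- !is.na(flag)
    sub <- sub[keep, , drop = FALSE]
    y <- flag[keep]
    ci <- if (config$se_method == "bootstrap")
      bootstrap_ci(y, sub$income, n_reps = config$n_boot,
                   seed = config$seed + match(w, waves),
                   rank_mode = config$rank_mode)
    else concentration_index(y, income = sub$income,
                             rank_mode = config$rank_mode)
    cindex_rows[[as.character(w)]] <- data.frame(
      wave = w, index = ci$index, se = ci$se,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      method = ci$method, n = ci$n)
    curves[[as.character(w)]] <-
      concentration_curve(y, income = sub$income,
                          rank_mode = config$rank_mode)
    dec <- tryCatch(
      decompose_cindex(sub, config$che, rank_mode = config$rank_mode),
      error = function(e) e)
    if (inherits(dec, "error"))
      errors[[paste0("decomposition_", w)]] <- conditionMessage(dec)
    else decomp[[as.character(w)]] <- dec
  }
  cindex <- do.call(rbind, cindex_rows)
  rownames(cindex) <- NULL

  strata <- if (length(config$strata))
    stratified_analysis(panel, config, config$strata) else NULL

  logistic <- tryCatch(fit_che_logistic(panel, config$che),
                       error = function(e) e)
  if (inherits(logistic, "error")) {
    errors[["logistic"]] <- conditionMessage(logistic)
    logistic <- NULL
  }
  quantile_fits <- tryCatch(che_quantile_regression(
    panel, config$che, taus = config$quantile_taus,
    n_boot = config$quantile_boot, seed = config$seed),
    error = function(e) e)
  if (inherits(quantile_fits, "error")) {
    errors[["quantile"]] <- conditionMessage(quantile_fits)
    quantile_fits <- NULL
  }

  bundle <- list(
    panel = panel, incidence = incidence, cindex = cindex,
    curves = curves, decomposition = decomp, strata = strata,
    logistic = logistic, quantile = quantile_fits,
    errors = if (length(errors)) errors else NULL,
    log = list(
      n_records = nrow(panel), n_excluded_ctp = n_excluded,
      seed = config$seed, rank_mode = config$rank_mode,
      se_method = config$se_method, threshold = config$che$threshold,
      waves = waves, r_version = as.character(getRversion()))
  )
  class(bundle) <- "che_run"
  bundle
}

#' @export
print.che_run <- function(x, ...) {
  cat("CHE inequality pipeline run\n")
  cat(sprintf("  %d records, %d excluded (CTP <= 0), threshold %.2f\n",
              x$log$n_records, x$log$n_excluded_ctp, x$log$threshold))
  print(x$incidence)
  cat("Concentration index by wave:\n")
  y <- x$cindex
  y$index <- round(y$index, 4); y$ci_low <- round(y$ci_low, 4)
  y$ci_high <- round(y$ci_high, 4); y$se <- round(y$se, 4)
  print.data.frame(y, row.names = FALSE)
  if (!is.null(x$errors)) {
    cat("stage failures (downstream dependents skipped):\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}

#' Heterogeneity analysis: per-stratum index and decomposition
#'
#' Splits the includable records by each requested stratum pair, recomputes
#' fractional income ranks within each stratum, and reports the
#' concentration index (with interval) and the probit decomposition per
#' stratum and wave. The two predicates of a split partition the includable
#' records; an empty stratum is skipped with a warning naming it.
#'
#' @param panel a `che_panel`.
#' @param config a [run_config()].
#' @param strata character vector of splits, see [run_config()].
#' @return nested list: `strata[[split]][[stratum]][[wave]]` with elements
#'   `n`, `cindex` and `decomposition`.
#' @export
stratified_analysis <- function(panel, config, strata = config$strata) {
  waves <- sort(unique(panel$wave))
  out <- list()
  for (split in strata) {
    preds <- stratum_predicates(split)
    out[[split]] <- list()
    for (sname in names(preds)) {
      sel <- preds[[sname]](panel)
      sub <- panel[sel, , drop = FALSE]
      if (nrow(sub) == 0L) {
        warning("empty stratum skipped: ", split, "/", sname, call. = FALSE)
        next
      }
      per_wave <- list()
      for (w in intersect(waves, unique(sub$wave))) {
        sw <- sub[sub$wave == w, , drop = FALSE]
        flag <- flag_che(sw, config$che)
        keep <- !is.na(flag)
        sw <- sw[keep, , drop = FALSE]
        y <- flag[keep]
        if (length(y) < 2L || sum(y) == 0L) {
          warning("stratum ", split, "/", sname, " wave ", w,
                  " too small or degenerate; skipped", call. = FALSE)
          next
        }
        ci <- concentration_index(y, income = sw$income,
                                  rank_mode = config$rank_mode)
        dec <- tryCatch(
          decompose_cindex(sw, config$che, rank_mode = config$rank_mode),
          error = function(e) e)
        per_wave[[as.character(w)]] <- list(
          n = length(y), cindex = ci,
          decomposition = if (inherits(dec, "error")) NULL else dec,
          decomposition_error = if (inherits(dec, "error"))
            conditionMessage(dec) else NULL)
      }
      out[[split]][[sname]] <- per_wave
    }
  }
  out
}

round_df <- function(df, index_cols = NULL, pct_cols = NULL) {
  for (cn in intersect(index_cols, names(df))) df[[cn]] <- round(df[[cn]], 4)
  for (cn in intersect(pct_cols, names(df))) df[[cn]] <- round(df[[cn]], 2)
  df
}

#' Render the run bundle as delimited-text and JSON tables
#'
#' Writes the per-wave incidence table, the concentration-index table, one
#' decomposition table per wave, the stratified index table, the logistic
#' odds-ratio table, the quantile-regression table, curve coordinates, and a
#' machine-readable JSON bundle. Indices are printed to 4 decimals and
#' percents to 2; every number is taken from the already-computed bundle (no
#' recomputation at render time).
#'
#' @param bundle a `che_run`.
#' @param dir output directory (created if needed).
#' @param format `"both"` (default), `"csv"` or `"json"`.
#' @return invisibly, the vector of files written.
#' @export
render_tables <- function(bundle, dir, format = c("both", "csv", "json")) {
  stopifnot(inherits(bundle, "che_run"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
  }

  json <- list()
  inc <- round_df(as.data.frame(bundle$incidence),
                  index_cols = c("incidence", "ci_low", "ci_high"))
  cidx <- round_df(as.data.frame(bundle$cindex),
                   index_cols = c("index", "se", "ci_low", "ci_high"))
  json$incidence <- inc
  json$cindex <- cidx

  decs <- list()
  for (w in names(bundle$decomposition)) {
    d <- bundle$decomposition[[w]]
    tab <- round_df(d$rows[, c("variable", "contribution", "percent",
                               "percent_excl_residual")],
                    index_cols = "contribution",
                    pct_cols = c("percent", "percent_excl_residual"))
    tab <- rbind(tab, data.frame(
      variable = "residual", contribution = round(d$residual, 4),
      percent = round(d$residual_percent, 2),
      percent_excl_residual = NA))
    decs[[w]] <- tab
    if (format != "json") wr(tab, paste0("decomposition_", w))
  }
  json$decomposition <- decs
  json$group_totals <- lapply(bundle$decomposition, function(d)
    as.list(round(d$group_totals, 2)))

  if (!is.null(bundle$strata)) {
    rows <- list()
    for (split in names(bundle$strata))
      for (sname in names(bundle$strata[[split]]))
        for (w in names(bundle$strata[[split]][[sname]])) {
          s <- bundle$strata[[split]][[sname]][[w]]
          rows[[length(rows) + 1L]] <- data.frame(
            split = split, stratum = sname, wave = w, n = s$n,
            index = s$cindex$index, ci_low = s$cindex$ci_low,
            ci_high = s$cindex$ci_high)
        }
    strat <- round_df(do.call(rbind, rows),
                      index_cols = c("index", "ci_low", "ci_high"))
    json$strata <- strat
    if (format != "json") wr(strat, "strata_cindex")
  }

  logi <- if (!is.null(bundle$logistic))
    round_df(bundle$logistic$table, pct_cols = c("or", "ci_low", "ci_high"))
  json$logistic <- logi

  qrows <- list()
  for (qn in names(bundle$quantile)) {
    f <- bundle$quantile[[qn]]
    cf <- data.frame(tau = f$tau, variable = names(f$coefficients),
                     estimate = round(f$coefficients, 4),
                     row.names = NULL)
    if (!is.null(f$ci)) {
      cf$ci_low <- round(f$ci[, 1], 4)
      cf$ci_high <- round(f$ci[, 2], 4)
    }
    qrows[[qn]] <- cf
  }
  qtab <- if (length(qrows)) do.call(rbind, qrows)
  if (!is.null(qtab)) rownames(qtab) <- NULL
  json$quantile <- qtab
  json$log <- bundle$log
  json$errors <- bundle$errors

  if (format != "json") {
    wr(inc, "incidence")
    wr(cidx, "cindex")
    if (!is.null(logi)) wr(logi, "logistic")
    if (!is.null(qtab)) wr(qtab, "quantile")
    for (w in names(bundle$curves))
      wr(as.data.frame(bundle$curves[[w]]), paste0("curve_", w))
  }
  if (format != "csv") {
    path <- file.path(dir, "bundle.json")
    jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    files <- c(files, path)
  }
  invisible(files)
}
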