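#' Configuration for the three-flag regime-shift diagnosis
#'
#' Collects every tunable parameter of the pipeline with the package defaults;
#' the resolved configuration is echoed into the report for provenance.
#'
#' @param tolerance,min_gap Consensus change-point parameters (years).
#' @param max_lag Largest F-to-SSB lag searched (years).
#' @param max_breaks Maximum structural breaks (hysteresis and SRR models).
#' @param alpha Significance level shared by the hysteresis branch test, the
#'   segmented-GLM break test and the threshold-GAM regime trends.
#' @param gap_min_frac Practical-significance guard of the loop classifier.
#' @param srr_candidates Candidate SRR model kinds for the LOOCV competition.
#' @param k_gam,k_tgam Basis dimensions of the plain and threshold GAM.
#' @param lower_q,upper_q,grid_size Threshold-search settings.
#' @param edf_min_gap,valley_depth Threshold-GAM decision settings.
#' @param temperature Whether to run the temperature flag: `TRUE`, `FALSE` or
#'   `"auto"` (run when an SST series is supplied).
#' @param seed Seed for the Bayesian change-point sampler.
#' @return A named list of class `flags_config`.
#' @export
flags_config <- function(tolerance = 1L, min_gap = 5L, max_lag = 10L,
                         max_breaks = 3L, alpha = 0.05, gap_min_frac = 0.25,
                         srr_candidates = c("linear", "loglog_linear",
                                            "ricker", "beverton_holt",
                                            "segmented_glm",
                                            "breakpoint_regression"),
                         k_gam = 3L, k_tgam = 4L, lower_q = 0.2,
                         upper_q = 0.8, grid_size = 20L, edf_min_gap = 0.5,
                         valley_depth = 0.05, temperature = "auto",
                         seed = 1L) {
  structure(list(tolerance = tolerance, min_gap = min_gap, max_lag = max_lag,
                 max_breaks = max_breaks, alpha = alpha,
                 gap_min_frac = gap_min_frac, srr_candidates = srr_candidates,
                 k_gam = k_gam, k_tgam = k_tgam, lower_q = lower_q,
                 upper_q = upper_q, grid_size = grid_size,
                 edf_min_gap = edf_min_gap, valley_depth = valley_depth,
                 temperature = temperature, seed = seed),
            class = "flags_config")
}

.flag_try <- function(expr) {
  tryCatch(list(ok = TRUE, value = expr, error = NULL),
           error = function(e) list(ok = FALSE, value = NULL,
                                    error = conditionMessage(e)))
}

#' Run the full three-flag regime-shift diagnosis on one stock
#'
#' Executes, in order: consensus change-point detection in SSB (abrupt-shift
#' flag), hysteresis classification of the lagged F-SSB relationship, the
#' stock-recruitment model competition (non-stationarity flag), and — when an
#' SST series is available — the temperature-threshold GAM decision. A
#' failure in one flag is recorded in the report without aborting the others;
#' only an invalid stock series aborts. The overall booleans are pure
#' functions of the component results: abrupt = at least one consensus
#' change; hysteresis = classification is a loop; non-stationary = a
#' discontinuous model wins the LOOCV competition with a supported break;
#' temperature = threshold verdict accepted.
#'
#' @param stock A [stock_series()].
#' @param env Optional [env_series()] of SST; required when the temperature
#'   flag is forced on.
#' @param config A [flags_config()].
#' @return A `regime_shift_report`: a serializable nested list, with the rich
#'   fitted objects attached in `attr(, "objects")`.
#' @export
run_three_flags <- function(stock, env = NULL, config = flags_config()) {
  validate_stock_series(stock)
  temp_on <- if (identical(config$temperature, "auto")) !is.null(env)
             else isTRUE(config$temperature)
  if (temp_on && is.null(env)) {
    abort("temperature flag enabled but no SST series supplied",
          class = "fishshift_config_error")
  }
  objects <- list()

  cps <- .flag_try({
    detect_ssb_changepoints(stock, tolerance = config$tolerance,
                            min_gap = config$min_gap, seed = config$seed)
  })
  flag_abrupt <- if (cps$ok) {
    objects$changepoints <- cps$value
    list(change_years = cps$value$change_years,
         periods = as.data.frame(cps$value$periods),
         binseg_years = cps$value$binseg$candidate_years,
         bayes_years = cps$value$bayes$candidate_years,
         error = NULL)
  } else list(change_years = integer(0), periods = NULL,
              binseg_years = NULL, bayes_years = NULL, error = cps$error)

  hy <- .flag_try({
    lag <- select_lag(stock$fmort, stock$ssb, max_lag = config$max_lag)
    bp <- fit_fssb_breakpoints(stock, lag, max_breaks = config$max_breaks)
    cls <- classify_hysteresis(stock, NULL, bp, alpha = config$alpha,
                               gap_min_frac = config$gap_min_frac)
    list(lag = lag, bp = bp, cls = cls)
  })
  flag_hysteresis <- if (hy$ok) {
    objects$hysteresis <- hy$value
    list(classification = hy$value$cls$classification,
         reason = hy$value$cls$reason,
         lag = hy$value$lag$lag,
         lag_correlation = hy$value$lag$correlation,
         branch_gap = hy$value$cls$branch_gap,
         p_value = hy$value$cls$p_value,
         break_years = hy$value$bp$break_years,
         segment_slopes = hy$value$bp$segment_coefficients$slope,
         error = NULL)
  } else list(classification = "failed", error = hy$error)

  sr <- .flag_try({
    srr <- align_srr(stock)
    comp <- loocv_compare(srr, candidates = config$srr_candidates)
    bp <- tryCatch(fit_srr_breakpoints(srr, max_breaks = config$max_breaks),
                   error = function(e) NULL)
    list(srr = srr, comp = comp, bp = bp)
  })
  flag_nonstationary <- if (sr$ok) {
    objects$srr <- sr$value
    win <- sr$value$comp$winner
    supported <- if (identical(win, "segmented_glm")) {
      p <- sr$value$comp$fits$segmented_glm$break_p_value
      isTRUE(is.finite(p) && p < config$alpha)
    } else if (identical(win, "breakpoint_regression")) {
      isTRUE(sr$value$comp$fits$breakpoint_regression$bp$n_breaks >= 1)
    } else TRUE
    list(winner = win,
         winner_break_supported = supported,
         comparison = as.data.frame(sr$value$comp$table),
         srr_break_years = if (!is.null(sr$value$bp))
           sr$value$bp$break_years else integer(0),
         error = NULL)
  } else list(winner = NA_character_, winner_break_supported = FALSE,
              error = sr$error)

  flag_temperature <- if (!temp_on) {
    list(enabled = FALSE, verdict = NA_character_, error = NULL)
  } else {
    tg <- .flag_try({
      srr <- align_srr(stock)
      assess_sst_threshold(srr, env, k_gam = config$k_gam,
                           k_tgam = config$k_tgam, lower_q = config$lower_q,
                           upper_q = config$upper_q,
                           grid_size = config$grid_size,
                           edf_min_gap = config$edf_min_gap,
                           alpha = config$alpha,
                           valley_depth = config$valley_depth)
    })
    if (tg$ok) {
      objects$tgam <- tg$value
      list(enabled = TRUE, verdict = tg$value$verdict,
           threshold = tg$value$threshold,
           loocv_prefers_tgam = tg$value$loocv_prefers_tgam,
           criteria = tg$value$criteria,
           edf_below = tg$value$edf_below, edf_above = tg$value$edf_above,
           error = NULL)
    } else list(enabled = TRUE, verdict = "failed", error = tg$error)
  }

  discontinuous <- c("segmented_glm", "breakpoint_regression")
  overall <- list(
    abrupt = length(flag_abrupt$change_years) >= 1,
    hysteresis = isTRUE(flag_hysteresis$classification %in%
                          c("closed_loop", "open_loop")),
    # a discontinuous winner flags non-stationarity only when its break is
    # itself supported (significant slope change, or >= 1 selected break):
    # the flexible discontinuous candidates win the training-RMSE rule almost
    # tautologically, so support of the break carries the evidence
    nonstationary = isTRUE(flag_nonstationary$winner %in% discontinuous) &&
      isTRUE(flag_nonstationary$winner_break_supported),
    temperature = isTRUE(identical(flag_temperature$verdict, "accepted"))
  )
  overall$n_flags <- sum(unlist(overall))

  report <- list(
    stock_id = attr(stock, "stock_id"),
    years = range(stock$year),
    flag_abrupt = flag_abrupt,
    flag_hysteresis = flag_hysteresis,
    flag_nonstationary = flag_nonstationary,
    flag_temperature = flag_temperature,
    overall = overall,
    config_echo = unclass(config),
    versions = list(fishshift = as.character(utils::packageVersion("fishshift")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    seed = config$seed
  )
  structure(report, class = "regime_shift_report", objects = objects)
}

#' @export
print.regime_shift_report <- function(x, ...) {
  cat(sprintf("<regime_shift_report> %s (%d-%d)\n", x$stock_id,
              x$years[1], x$years[2]))
  o <- x$overall
  cat(sprintf("  abrupt shifts: %s | hysteresis: %s | non-stationary SRR: %s | SST threshold: %s\n",
              o$abrupt, o$hysteresis, o$nonstationary, o$temperature))
  cat(sprintf("  flags raised: %d\n", o$n_flags))
  invisible(x)
}

#' Recompute the overall flag booleans from a report's component results
#'
#' @param report A `regime_shift_report` (or one re-read from JSON).
#' @return A named list matching `report$overall`.
#' @export
recompute_overall_flags <- function(report) {
  out <- list(
    abrupt = length(report$flag_abrupt$change_years) >= 1,
    hysteresis = isTRUE(report$flag_hysteresis$classification %in%
                          c("closed_loop", "open_loop")),
    nonstationary = isTRUE(report$flag_nonstationary$winner %in%
                             c("segmented_glm", "breakpoint_regression")) &&
      isTRUE(report$flag_nonstationary$winner_break_supported),
    temperature = isTRUE(identical(report$flag_temperature$verdict,
                                   "accepted"))
  )
  out$n_flags <- sum(unlist(out))
  out
}

#' Write a regime-shift report to JSON (plus companion CSV tables)
#'
#' The JSON document has stable key order and full numeric precision, so two
#' writes of the same report are byte-identical. Companion CSVs for the SSB
#' periods, the F-SSB segments and the SRR model comparison are written next
#' to the JSON file (same stem).
#'
#' @param report A `regime_shift_report`.
#' @param path Output JSON path.
#' @param csv Also write the companion CSV tables (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = TRUE) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  if (csv) {
    stem <- sub("\\.json$", "", path)
    per <- report$flag_abrupt$periods
    if (!is.null(per)) {
      readr::write_csv(as.data.frame(per), paste0(stem, "_periods.csv"))
    }
    comp <- report$flag_nonstationary$comparison
    if (!is.null(comp)) {
      readr::write_csv(as.data.frame(comp), paste0(stem, "_model_comparison.csv"))
    }
    hys <- report$flag_hysteresis
    if (!is.null(hys$segment_slopes)) {
      readr::write_csv(
        tibble(segment = seq_along(hys$segment_slopes),
               slope = hys$segment_slopes),
        paste0(stem, "_fssb_segments.csv"))
    }
  }
  invisible(path)
}

#' Read a regime-shift report back from JSON
#'
#' @param path Path written by [write_report()].
#' @return A `regime_shift_report` (without the rich fitted objects).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "fishshift_input_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "regime_shift_report")
}
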