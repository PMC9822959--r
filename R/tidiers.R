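#' @export
tidy.cpt_result <- function(x, ...) {
  if (!is.null(x$posterior_trace)) {
    x$posterior_trace
  } else {
    tibble(year = x$candidate_years, score = x$scores)
  }
}

#' @export
glance.cpt_result <- function(x, ...) {
  tibble(method = x$method, n_candidates = length(x$candidate_years))
}

#' @export
tidy.consensus_cpts <- function(x, ...) x$periods

#' @export
glance.consensus_cpts <- function(x, ...) {
  tibble(n_changes = length(x$change_years),
         n_periods = nrow(x$periods))
}

#' @export
tidy.lag_selection <- function(x, ...) x$correlogram

#' @export
glance.lag_selection <- function(x, ...) {
  tibble(lag = x$lag, correlation = x$correlation)
}

#' @export
tidy.breakpoint_model <- function(x, ...) x$segment_coefficients

#' @export
glance.breakpoint_model <- function(x, ...) {
  tibble(n_breaks = x$n_breaks, rss = x$rss,
         bic = x$information_criterion$bic[x$n_breaks + 1])
}

#' @export
tidy.hysteresis_assessment <- function(x, ...) {
  x$bins %||% tibble()
}

#' @export
glance.hysteresis_assessment <- function(x, ...) {
  tibble(classification = x$classification, lag = x$lag,
         branch_gap = x$branch_gap, p_value = x$p_value)
}

#' @export
tidy.srr_fit <- function(x, ...) {
  out <- tibble(term = c("alpha", "beta", "psi"),
                estimate = c(x$alpha, x$beta, x$psi))
  out[!is.na(out$estimate), ]
}

#' @export
glance.srr_fit <- function(x, ...) {
  tibble(model_kind = x$model_kind, sse = x$sse, sse_scale = x$sse_scale,
         n = nrow(x$data),
         rmse_raw = sqrt(mean((x$fitted - x$data$r)^2)))
}

#' @export
tidy.model_comparison <- function(x, ...) x$table

#' @export
glance.model_comparison <- function(x, ...) {
  w <- x$table[x$table$model_kind == x$winner, ]
  tibble(winner = x$winner, rmse_train = w$rmse_train,
         rmse_test = w$rmse_test)
}

#' @export
tidy.gam_fit <- function(x, ...) x$gcv_path

#' @export
glance.gam_fit <- function(x, ...) {
  tibble(k = x$k, lambda = x$lambda, edf = x$edf, gcv = x$gcv)
}

#' @export
tidy.tgam_fit <- function(x, ...) x$gcv_profile

#' @export
glance.tgam_fit <- function(x, ...) {
  tibble(threshold = x$threshold, gcv = x$gcv,
         edf_below = x$edf_below, edf_above = x$edf_above,
         slope_p_below = x$slope_p_below, slope_p_above = x$slope_p_above,
         resid_acf1 = x$resid_acf1)
}

#' @export
glance.tgam_decision <- function(x, ...) {
  tibble(verdict = x$verdict, threshold = x$threshold,
         loocv_prefers_tgam = x$loocv_prefers_tgam,
         edf_differ = x$criteria$edf_differ,
         any_slope_significant = x$criteria$any_slope_significant,
         gcv_valley = x$criteria$gcv_valley)
}

#' @export
glance.regime_shift_report <- function(x, ...) {
  tibble(stock_id = x$stock_id,
         abrupt = x$overall$abrupt, hysteresis = x$overall$hysteresis,
         nonstationary = x$overall$nonstationary,
         temperature = x$overall$temperature,
         n_flags = x$overall$n_flags)
}
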