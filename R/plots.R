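#' Plot a stock series with optional consensus periods
#'
#' Three stacked panels — F, SSB and recruitment — with the consensus SSB
#' periods shaded and management reference points drawn as horizontal lines
#' where supplied.
#'
#' @param series A [stock_series()].
#' @param consensus Optional `consensus_cpts` to shade SSB periods.
#' @param refpts Optional [reference_points()] for annotation only.
#' @return A ggplot object.
#' @export
plot_stock_series <- function(series, consensus = NULL, refpts = NULL) {
  long <- tidyr::pivot_longer(
    as_tibble(series), c("fmort", "ssb", "recruitment"),
    names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, levels = c("fmort", "ssb", "recruitment"),
                          labels = c("F (per year)", "SSB (tonnes)",
                                     "R (thousands)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL, title = attr(series, "stock_id")) +
    ggplot2::theme_minimal()
  if (!is.null(consensus) && length(consensus$change_years) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = consensus$change_years,
                                 linetype = "dashed", colour = "grey40")
  }
  if (!is.null(refpts)) {
    rp <- tidyr::pivot_longer(as_tibble(refpts), dplyr::everything())
    rp <- rp[!is.na(rp$value), ]
    rp$quantity <- ifelse(grepl("^f_", rp$name), "F (per year)", "SSB (tonnes)")
    rp$quantity <- factor(rp$quantity, levels = levels(long$quantity))
    p <- p + ggplot2::geom_hline(data = rp,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}

#' @method autoplot cpt_result
#' @export
autoplot.cpt_result <- function(object, ...) {
  if (is.null(object$posterior_trace)) {
    dat <- tibble(year = object$candidate_years, score = object$scores)
    return(ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$score)) +
             ggplot2::geom_col(width = 0.6) +
             ggplot2::labs(x = "Year", y = "Penalized gain",
                           title = "Binary-segmentation candidates") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(object$posterior_trace,
                  ggplot2::aes(.data$year, .data$prob)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$declare_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Year", y = "Posterior change probability",
                  title = "Bayesian change-point posterior") +
    ggplot2::theme_minimal()
}

#' @method autoplot consensus_cpts
#' @export
autoplot.consensus_cpts <- function(object, ...) {
  per <- object$periods
  per$period <- factor(seq_len(nrow(per)))
  ggplot2::ggplot(per) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_year,
                                    xmax = .data$end_year + 1,
                                    ymin = 0, ymax = 1,
                                    fill = .data$period), alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$change_years,
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Year", y = NULL,
                  title = "Quasi-stable periods from consensus change points") +
    ggplot2::theme_minimal()
}

#' @method autoplot lag_selection
#' @export
autoplot.lag_selection <- function(object, ...) {
  ggplot2::ggplot(object$correlogram,
                  ggplot2::aes(.data$lag, .data$correlation)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::geom_col(data = object$correlogram[object$correlogram$lag ==
                                                  object$lag, ],
                      fill = "firebrick", width = 0.5) +
    ggplot2::labs(x = "Lag of F ahead of SSB (years)",
                  y = "Cross-correlation") +
    ggplot2::theme_minimal()
}

#' @method autoplot hysteresis_assessment
#' @export
autoplot.hysteresis_assessment <- function(object, ...) {
  if (is.null(object$bins)) {
    abort("no branch bins available to plot (classification was early-exit)",
          class = "fishshift_input_error")
  }
  long <- tidyr::pivot_longer(object$bins, c("ssb_ascending", "ssb_descending"),
                              names_to = "branch", values_to = "ssb")
  long$branch <- sub("ssb_", "", long$branch)
  ggplot2::ggplot(long, ggplot2::aes((.data$f_lo + .data$f_hi) / 2, .data$ssb,
                                     colour = .data$branch)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lagged F (per year)", y = "Mean SSB (tonnes)",
                  title = paste("Hysteresis:", object$classification)) +
    ggplot2::theme_minimal()
}

#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("rmse_train", "rmse_test"),
                              names_to = "set", values_to = "rmse")
  long$set <- sub("rmse_", "", long$set)
  ggplot2::ggplot(long, ggplot2::aes(.data$model_kind, .data$rmse,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "LOOCV RMSE (raw recruitment scale)",
                  title = paste("SRR competition - winner:", object$winner)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @method autoplot tgam_fit
#' @export
autoplot.tgam_fit <- function(object, ...) {
  dat <- object$data
  dat$regime <- ifelse(object$below, "below threshold (cold)",
                       "above threshold (warm)")
  dat$fitted <- object$fitted
  ggplot2::ggplot(dat, ggplot2::aes(.data$s, .data$r,
                                    colour = .data$regime)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::scale_colour_manual(values = c("below threshold (cold)" = "blue3",
                                            "above threshold (warm)" = "red3")) +
    ggplot2::labs(x = "SSB (tonnes)", y = "Recruitment (thousands)",
                  title = sprintf("Threshold GAM (SST threshold %.2f degC)",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}

#' GCV profile of a threshold-GAM fit
#'
#' The "valley plot" behind the third decision criterion: GCV of the best
#' two-regime model per candidate SST threshold.
#'
#' @param fit A `tgam_fit`.
#' @return A ggplot object.
#' @export
plot_gcv_profile <- function(fit) {
  ggplot2::ggplot(fit$gcv_profile, ggplot2::aes(.data$threshold, .data$gcv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = fit$threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Candidate SST threshold (degC)", y = "GCV") +
    ggplot2::theme_minimal()
}
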