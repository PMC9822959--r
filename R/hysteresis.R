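#' Select the lag of the fishing-mortality effect on SSB
#'
#' Fishing pressure rarely affects spawning biomass instantaneously. This
#' computes the sample cross-correlation of F leading SSB at lags
#' `0..max_lag` (pairs mean-centred and normalised over each lag's overlap)
#' and returns the lag with the maximal absolute correlation; ties break
#' toward the smaller lag.
#'
#' @param fmort Fishing mortality series (per year).
#' @param ssb SSB series (tonnes), same years.
#' @param max_lag Largest lag searched, years (default 10).
#' @return A `lag_selection` list: `lag`, `correlation` and the full
#'   `correlogram` tibble.
#' @export
select_lag <- function(fmort, ssb, max_lag = 10L) {
  if (length(fmort) != length(ssb)) {
    abort("fmort and ssb must be equally long", class = "fishshift_input_error")
  }
  if (max_lag < 0) abort("max_lag must be >= 0",
                         class = "fishshift_input_error")
  n <- length(ssb)
  if (n - max_lag < 10) {
    abort("need at least 10 overlapping observations after lagging",
          class = "fishshift_input_error")
  }
  cors <- vapply(0:max_lag, function(L) {
    x <- fmort[seq_len(n - L)]
    y <- ssb[seq_len(n - L) + L]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      abort("zero-variance input in lag search",
            class = "fishshift_input_error")
    }
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  best <- which.max(abs(cors)) # first max: ties go to the smaller lag
  structure(list(lag = best - 1L, correlation = cors[best],
                 correlogram = tibble(lag = 0:max_lag, correlation = cors)),
            class = "lag_selection")
}

#' @export
print.lag_selection <- function(x, ...) {
  cat(sprintf("<lag_selection> lag = %d years (r = %.3f)\n",
              x$lag, x$correlation))
  invisible(x)
}

# RSS of the OLS fit of y on x over a contiguous index window; falls back to
# intercept-only when the predictor is degenerate in that window
.window_rss <- function(px, py, pxx, pxy, pyy, s, e) {
  len <- e - s + 1
  sx <- px[e + 1] - px[s]; sy <- py[e + 1] - py[s]
  sxx <- pxx[e + 1] - pxx[s]; sxy <- pxy[e + 1] - pxy[s]
  syy <- pyy[e + 1] - pyy[s]
  cxx <- sxx - sx^2 / len
  cyy <- syy - sy^2 / len
  if (cxx <= 1e-10 * max(1, sxx)) {
    c(rss = max(cyy, 0), degenerate = 1)
  } else {
    cxy <- sxy - sx * sy / len
    c(rss = max(cyy - cxy^2 / cxx, 0), degenerate = 0)
  }
}

#' Bai-Perron multiple structural breaks in a linear regression
#'
#' Exact dynamic programming over all admissible segmentations of the
#' observation order: for each number of breaks `m` up to `max_breaks`, finds
#' the segmentation minimising the total residual sum of squares of
#' per-segment OLS fits of `y` on `x`; the reported `m` minimises the BIC.
#' Deterministic. Segments with a degenerate (constant) predictor fall back to
#' an intercept-only fit and are flagged.
#'
#' @param x Predictor series, in observation (temporal) order.
#' @param y Response series.
#' @param max_breaks Largest number of breaks considered.
#' @param min_segment_fraction Minimum segment size as a fraction of `n`
#'   (never fewer than 3 observations).
#' @return A `breakpoint_model`: `n_breaks`, `break_indices` (last index of
#'   each segment but the final one), `segment_coefficients`, `rss` and the
#'   per-`m` `information_criterion` tibble.
#' @export
baiperron_breakpoints <- function(x, y, max_breaks = 3L,
                                  min_segment_fraction = 0.15) {
  n <- length(y)
  if (length(x) != n) abort("x and y must be equally long",
                            class = "fishshift_input_error")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("x and y must be finite", class = "fishshift_input_error")
  }
  min_seg <- max(3L, as.integer(ceiling(min_segment_fraction * n)))
  if (n < (max_breaks + 1) * min_seg) {
    abort(sprintf(
      "need n >= %d for max_breaks = %d at min segment %d",
      (max_breaks + 1) * min_seg, max_breaks, min_seg),
      class = "fishshift_input_error")
  }
  px <- c(0, cumsum(x)); py <- c(0, cumsum(y))
  pxx <- c(0, cumsum(x^2)); pxy <- c(0, cumsum(x * y))
  pyy <- c(0, cumsum(y^2))
  rss_win <- matrix(Inf, n, n)
  for (s in seq_len(n - min_seg + 1)) {
    for (e in seq(s + min_seg - 1, n)) {
      rss_win[s, e] <- .window_rss(px, py, pxx, pxy, pyy, s, e)[["rss"]]
    }
  }
  # dp[m+1, j]: minimal RSS of splitting 1..j into m+1 segments
  dp <- matrix(Inf, max_breaks + 1, n)
  arg <- matrix(NA_integer_, max_breaks + 1, n)
  dp[1, ] <- rss_win[1, ]
  if (max_breaks >= 1) {
    for (m in seq_len(max_breaks)) {
      for (j in seq(((m + 1) * min_seg), n)) {
        ks <- seq(m * min_seg, j - min_seg)
        tot <- dp[m, ks] + rss_win[ks + 1, j]
        kbest <- ks[which.min(tot)]
        dp[m + 1, j] <- min(tot)
        arg[m + 1, j] <- kbest
      }
    }
  }
  rss_m <- dp[, n]
  # floor relative to the response scale so exact fits tie and resolve to the
  # smallest break count by penalty alone
  tss <- .window_rss(px, py, pxx, pxy, pyy, 1, n)[["rss"]] +
    (py[n + 1] / n)^2 * n
  bic <- n * log(pmax(rss_m / n, 1e-10 * (tss / n + 1e-300))) +
    (2 * (seq_along(rss_m)) + (seq_along(rss_m) - 1)) * log(n)
  m_sel <- which.min(bic) - 1L
  # backtrack the selected segmentation
  breaks <- integer(0)
  j <- n
  if (m_sel > 0) {
    for (m in seq(m_sel, 1)) {
      k <- arg[m + 1, j]
      breaks <- c(k, breaks)
      j <- k
    }
  }
  bounds <- c(0L, breaks, n)
  seg <- purrr::map_dfr(seq_len(m_sel + 1), function(i) {
    s <- bounds[i] + 1L; e <- bounds[i + 1]
    w <- .window_rss(px, py, pxx, pxy, pyy, s, e)
    if (w[["degenerate"]] == 1) {
      tibble(segment = i, start_idx = s, end_idx = e,
             intercept = mean(y[s:e]), slope = NA_real_,
             intercept_only = TRUE)
    } else {
      fit <- lm(y[s:e] ~ x[s:e])
      tibble(segment = i, start_idx = s, end_idx = e,
             intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
             intercept_only = FALSE)
    }
  })
  structure(list(
    n_breaks = m_sel,
    break_indices = breaks,
    segment_coefficients = seg,
    rss = rss_m[m_sel + 1],
    information_criterion = tibble(m = seq_along(rss_m) - 1L,
                                   rss = rss_m, bic = bic),
    min_segment = min_seg
  ), class = "breakpoint_model")
}

#' @export
print.breakpoint_model <- function(x, ...) {
  cat(sprintf("<breakpoint_model> %d break(s), RSS = %.4g\n",
              x$n_breaks, x$rss))
  print(x$segment_coefficients)
  invisible(x)
}

#' Structural breaks in the lagged F-SSB relationship
#'
#' Pairs each year's SSB with the fishing mortality `lag` years earlier, keeps
#' the pairs in temporal order, and applies [baiperron_breakpoints()] with
#' `y = SSB_t` and `x = F_(t-lag)`. The resulting segments are temporal phases
#' of the pressure-state relationship.
#'
#' @param series A [stock_series()].
#' @param lag A `lag_selection` from [select_lag()], or an integer lag;
#'   `NULL` selects the lag automatically.
#' @param max_breaks Maximum number of breaks.
#' @param min_segment_fraction Passed to [baiperron_breakpoints()].
#' @return A `breakpoint_model` with an extra `years` element mapping
#'   observation indices to calendar years, and `lag` used.
#' @export
fit_fssb_breakpoints <- function(series, lag = NULL, max_breaks = 3L,
                                 min_segment_fraction = 0.15) {
  validate_stock_series(series)
  if (is.null(lag)) lag <- select_lag(series$fmort, series$ssb)
  L <- if (inherits(lag, "lag_selection")) lag$lag else as.integer(lag)
  n <- nrow(series)
  idx <- seq(L + 1L, n)
  x <- series$fmort[idx - L]
  y <- series$ssb[idx]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 15) {
    abort("need at least 15 lagged (F, SSB) pairs",
          class = "fishshift_input_error")
  }
  fit <- baiperron_breakpoints(x[ok], y[ok], max_breaks = max_breaks,
                               min_segment_fraction = min_segment_fraction)
  fit$years <- series$year[idx][ok]
  fit$lag <- L
  fit$break_years <- fit$years[fit$break_indices]
  fit
}

# core loop classifier at one fixed lag
.classify_at_lag <- function(series, L, breaks, alpha, n_bins, gap_min_frac,
                             final_window, collapse_frac = 0.5) {
  n <- nrow(series)
  idx <- seq(L + 1L, n)
  f <- series$fmort[idx - L]
  b <- series$ssb[idx]
  ok <- !is.na(f) & !is.na(b)
  f <- f[ok]; b <- b[ok]
  sign_pattern <- if (!is.null(breaks)) {
    sign(breaks$segment_coefficients$slope)
  } else NA
  out <- function(classification, reason, gap = NA_real_, p = NA_real_,
                  bins = NULL, extras = list()) {
    structure(c(list(classification = classification, reason = reason,
                     branch_gap = gap, p_value = p, alpha = alpha,
                     lag = L, segments_sign_pattern = sign_pattern,
                     bins = bins), extras),
              class = "hysteresis_assessment")
  }
  f_smooth <- as.numeric(stats::filter(f, rep(1 / 3, 3), sides = 2))
  f_smooth[is.na(f_smooth)] <- f[is.na(f_smooth)]
  peak <- which.max(f_smooth)
  if (peak <= 2 || peak >= length(f) - 1) {
    return(out("none", "monotone pressure"))
  }
  asc <- seq_len(peak)
  desc <- seq(peak + 1L, length(f))
  lo <- max(min(f[asc]), min(f[desc]))
  hi <- min(max(f[asc]), max(f[desc]))
  if (!(hi > lo)) return(out("indeterminate", "branches share no F range"))
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin_of <- function(v) {
    k <- findInterval(v, edges, rightmost.closed = TRUE)
    k[v < lo | v > hi] <- 0L
    k
  }
  ba <- bin_of(f[asc]); bd <- bin_of(f[desc])
  shared_bins <- intersect(unique(ba[ba >= 1]), unique(bd[bd >= 1]))
  if (length(shared_bins) < n_bins) {
    return(out("indeterminate",
               sprintf("branches co-occupy only %d of %d F bins",
                       length(shared_bins), n_bins)))
  }
  bins <- purrr::map_dfr(sort(shared_bins), function(k) {
    tibble(bin = k, f_lo = edges[k], f_hi = edges[k + 1],
           ssb_ascending = mean(b[asc[ba == k]]),
           ssb_descending = mean(b[desc[bd == k]]))
  })
  gap <- mean(bins$ssb_descending - bins$ssb_ascending)
  tt <- tryCatch(t.test(bins$ssb_descending, bins$ssb_ascending,
                        paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) return(out("indeterminate", "branch test failed",
                              gap = gap, bins = bins))
  significant <- tt$p.value < alpha &&
    abs(gap) >= gap_min_frac * diff(range(b))
  # pre-collapse period: ascending years before SSB first fell below
  # collapse_frac of its running maximum
  runmax <- cummax(b[asc])
  coll <- which(b[asc] < collapse_frac * runmax)
  pre <- if (length(coll) > 0) asc[seq_len(max(coll[1] - 1L, 1L))] else asc
  pre_min <- min(b[pre])
  f_sustain <- max(f[pre])
  fin <- seq(max(1L, n - final_window + 1L), n)
  fin_ssb <- mean(series$ssb[fin], na.rm = TRUE)
  fin_f <- mean(series$fmort[fin], na.rm = TRUE)
  extras <- list(pre_collapse_min = pre_min, f_sustain = f_sustain,
                 final_ssb = fin_ssb, final_f = fin_f)
  if (!significant) {
    return(out("none", "no significant branch separation",
               gap = gap, p = tt$p.value, bins = bins, extras = extras))
  }
  if (fin_ssb >= pre_min) {
    out("closed_loop", "significant loop; final SSB re-enters pre-collapse range",
        gap = gap, p = tt$p.value, bins = bins, extras = extras)
  } else if (fin_f <= f_sustain) {
    out("open_loop",
        "significant loop; SSB below pre-collapse minimum despite reduced F",
        gap = gap, p = tt$p.value, bins = bins, extras = extras)
  } else {
    out("indeterminate", "SSB depressed but F still above pre-collapse level",
        gap = gap, p = tt$p.value, bins = bins, extras = extras)
  }
}

#' Classify a stock trajectory for hysteresis in the F-SSB relationship
#'
#' Operationalizes the visual loop diagnosis. The trajectory of lagged F
#' versus SSB is split at the year of maximum (3-year smoothed) F into an
#' ascending-pressure and a descending-pressure branch. Over the F range the
#' branches share, SSB is compared between branches inside `n_bins`
#' equal-width F bins: `branch_gap` is the mean descending-minus-ascending
#' SSB difference across the matched bins, tested by a paired t-test across
#' bins. A loop is declared only when that test is significant at `alpha`
#' *and* the gap exceeds `gap_min_frac` of the observed SSB range (a
#' practical-significance guard against transient branch lag). A significant
#' loop is `closed_loop` when the final period's SSB re-enters the
#' pre-collapse range, `open_loop` when it stays below the pre-collapse
#' minimum although final F is at or below the level that previously
#' sustained that SSB.
#'
#' Because the cross-correlation lag is, by construction, the shift that makes
#' SSB most nearly a single-valued function of F, it can flatten a genuine
#' loop; with `lag = NULL` the classifier therefore evaluates both the
#' selected lag and lag 0 and reports the assessment with the larger absolute
#' branch gap.
#'
#' @param series A [stock_series()].
#' @param lag A `lag_selection`, an integer lag, or `NULL` (compare the
#'   selected lag with lag 0 as described above).
#' @param breaks Optional `breakpoint_model` from [fit_fssb_breakpoints()]
#'   used only to report the segment slope-sign pattern.
#' @param alpha Significance level of the paired branch test.
#' @param n_bins Number of equal-width F bins over the shared range.
#' @param gap_min_frac Minimum |branch gap| as a fraction of the SSB range.
#' @param final_window Years defining the "final period" (default 5).
#' @return A `hysteresis_assessment` list with `classification` (one of
#'   `none`, `closed_loop`, `open_loop`, `indeterminate`), `branch_gap`,
#'   `p_value`, `segments_sign_pattern` and supporting quantities.
#' @export
classify_hysteresis <- function(series, lag = NULL, breaks = NULL,
                                alpha = 0.05, n_bins = 5L,
                                gap_min_frac = 0.25, final_window = 5L) {
  validate_stock_series(series)
  if (is.null(breaks)) {
    breaks <- tryCatch(fit_fssb_breakpoints(series, lag),
                       error = function(e) NULL)
  }
  if (is.null(lag)) {
    sel <- select_lag(series$fmort, series$ssb)
    cands <- unique(c(sel$lag, 0L))
  } else {
    cands <- if (inherits(lag, "lag_selection")) lag$lag else as.integer(lag)
  }
  res <- purrr::map(cands, function(L) {
    .classify_at_lag(series, L, breaks, alpha, n_bins, gap_min_frac,
                     final_window)
  })
  gaps <- vapply(res, function(r) {
    if (is.finite(r$branch_gap)) abs(r$branch_gap) else -Inf
  }, numeric(1))
  if (all(!is.finite(gaps))) return(res[[1]])
  res[[which.max(gaps)]]
}

#' @export
print.hysteresis_assessment <- function(x, ...) {
  cat(sprintf("<hysteresis_assessment> %s (lag %d)\n  %s\n",
              x$classification, x$lag, x$reason))
  if (is.finite(x$branch_gap)) {
    cat(sprintf("  branch gap %.4g, paired p = %.3g\n", x$branch_gap,
                x$p_value))
  }
  invisible(x)
}
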