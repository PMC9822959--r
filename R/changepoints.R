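#' @section Change-point detection:
#' Abrupt shifts in SSB (the first regime-shift flag) are detected by two
#' independent algorithms — a Bayesian product-partition sampler giving a
#' per-year posterior change probability, and penalized binary segmentation —
#' and then combined by a consensus rule: a change is retained only where both
#' methods agree within a year tolerance, and consecutive changes must be at
#' least `min_gap` years apart so the periods between them are quasi-stable.
#' @name changepoints
NULL

# Gauss-Legendre nodes/weights on (0, upper), Golub-Welsch on the Jacobi matrix
.gauss_legendre <- function(n_nodes, upper) {
  k <- seq_len(n_nodes - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n_nodes, n_nodes)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  eig <- eigen(J, symmetric = TRUE)
  nodes <- eig$values
  weights <- 2 * eig$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = upper * (nodes[ord] + 1) / 2, weights = upper * weights[ord] / 2)
}

.new_cpt_result <- function(method, candidate_years, scores, posterior_trace,
                            params) {
  structure(list(method = method,
                 candidate_years = as.integer(candidate_years),
                 scores = as.numeric(scores),
                 posterior_trace = posterior_trace,
                 params = params),
            class = "cpt_result")
}

#' @export
print.cpt_result <- function(x, ...) {
  cat("<cpt_result> method:", x$method, "\n")
  if (length(x$candidate_years) == 0) {
    cat("  no candidate change years\n")
  } else {
    cat("  candidate years:", paste(x$candidate_years, collapse = ", "), "\n")
    cat("  scores:", paste(signif(x$scores, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bayesian change-point posterior for a series mean
#'
#' Gibbs sampler over the Barry-Hartigan product-partition model for changes
#' in mean: every interior boundary of the series carries an indicator that is
#' resampled from its full conditional given all others, with uniform priors
#' on `(0, prior_p0)` for the boundary probability and `(0, prior_w0)` for the
#' signal-to-noise ratio. The per-position posterior change probability is the
#' fraction of post-burn-in sweeps in which that boundary is active. The run
#' is deterministic given `seed`.
#'
#' @param values Numeric series (e.g. annual SSB).
#' @param years Optional calendar years (defaults to `1..n`). A change at
#'   boundary `t` is reported as the first year of the new period.
#' @param prior_p0,prior_w0 Upper limits of the uniform priors, in (0, 1).
#' @param iterations,burnin Total Gibbs sweeps and discarded initial sweeps.
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param declare_threshold Posterior probability above which a position is
#'   reported as a candidate change.
#' @return A `cpt_result` with `candidate_years`, posterior `scores` and the
#'   full `posterior_trace` tibble (`year`, `prob`).
#' @export
bcp_posterior <- function(values, years = NULL, prior_p0 = 0.2,
                          prior_w0 = 0.2, iterations = 5000L, burnin = 500L,
                          seed = NULL, declare_threshold = 0.5) {
  n <- length(values)
  if (n < 5) abort("series must have length >= 5",
                   class = "fishshift_input_error")
  if (any(!is.finite(values))) {
    abort("series contains non-finite values", class = "fishshift_input_error")
  }
  if (iterations <= burnin) {
    abort("iterations must exceed burnin", class = "fishshift_input_error")
  }
  if (prior_p0 <= 0 || prior_p0 >= 1 || prior_w0 <= 0 || prior_w0 >= 1) {
    abort("priors must lie in (0, 1)", class = "fishshift_input_error")
  }
  years <- if (is.null(years)) seq_len(n) else as.integer(years)
  params <- list(prior_p0 = prior_p0, prior_w0 = prior_w0,
                 iterations = iterations, burnin = burnin, seed = seed,
                 declare_threshold = declare_threshold)
  if (var(values) == 0) {
    warn("series has zero variance; returning all-zero posteriors")
    trace <- tibble(year = years[-1], prob = rep(0, n - 1))
    return(.new_cpt_result("bayesian", integer(0), numeric(0), trace, params))
  }
  if (!is.null(seed)) set.seed(seed)
  gl <- .gauss_legendre(24L, prior_w0)
  probs <- bcp_gibbs_cpp(as.numeric(values), prior_p0, prior_w0,
                         as.integer(iterations), as.integer(burnin),
                         gl$nodes, gl$weights)
  # boundary i sits between years[i] and years[i + 1]; the change year is the
  # first year of the new period
  trace <- tibble(year = years[-1], prob = as.numeric(probs))
  keep <- which(trace$prob >= declare_threshold)
  .new_cpt_result("bayesian", trace$year[keep], trace$prob[keep], trace, params)
}

.seg_rss <- function(cs, cs2, s, e) {
  len <- e - s + 1
  sum_x <- cs[e + 1] - cs[s]
  (cs2[e + 1] - cs2[s]) - sum_x^2 / len
}

#' Binary segmentation for changes in mean
#'
#' Greedy binary segmentation under a Gaussian mean-change cost: at each step
#' the split giving the largest reduction in within-segment sum of squares is
#' proposed; it is accepted only if the likelihood-ratio gain
#' `(RSS_parent - RSS_left - RSS_right) / sigma^2` exceeds `penalty` and both
#' child segments contain at least `min_segment` observations. The noise
#' scale `sigma^2` is estimated robustly from first differences (median
#' absolute deviation), so step changes do not inflate it, and the gain is
#' invariant to adding a constant to, or positively rescaling, the series.
#'
#' @param values Numeric series.
#' @param years Optional calendar years. A change is reported as the first
#'   year of the new segment.
#' @param max_changes Maximum number of change points (default 5).
#' @param min_segment Minimum segment length in years; defaults to 5, the
#'   quasi-stability rule also used by the consensus step.
#' @param penalty Acceptance threshold for the penalized gain; default is the
#'   MBIC-style `3 * log(n)`.
#' @return A `cpt_result` with candidate years and their gains as scores.
#' @export
binseg_changepoints <- function(values, years = NULL, max_changes = 5L,
                                min_segment = 5L, penalty = NULL) {
  n <- length(values)
  if (any(!is.finite(values))) {
    abort("series contains non-finite values", class = "fishshift_input_error")
  }
  if (n < 2 * min_segment) {
    abort("series must have length >= 2 * min_segment",
          class = "fishshift_input_error")
  }
  if (max_changes < 1) {
    abort("max_changes must be >= 1", class = "fishshift_input_error")
  }
  years <- if (is.null(years)) seq_len(n) else as.integer(years)
  if (is.null(penalty)) penalty <- 3 * log(n)
  cs <- c(0, cumsum(values))
  cs2 <- c(0, cumsum(values^2))
  # robust noise scale: step changes affect few first differences, so the MAD
  # of diffs estimates sigma without the signal
  sigma2 <- (stats::mad(diff(values))^2) / 2
  sigma2 <- max(sigma2, 1e-12 * mean(values^2), 1e-300)

  best_split <- function(s, e) {
    ks <- seq(s + min_segment - 1, e - min_segment)
    if (length(ks) == 0 || ks[1] > ks[length(ks)]) return(NULL)
    child <- vapply(ks, function(k) {
      .seg_rss(cs, cs2, s, k) + .seg_rss(cs, cs2, k + 1, e)
    }, numeric(1))
    k <- ks[which.min(child)]
    parent <- .seg_rss(cs, cs2, s, e)
    list(k = k, gain = max(parent - min(child), 0) / sigma2)
  }

  segments <- list(c(1L, n))
  found_pos <- integer(0)
  found_gain <- numeric(0)
  while (length(found_pos) < max_changes) {
    props <- lapply(segments, function(se) best_split(se[1], se[2]))
    gains <- vapply(props, function(p) if (is.null(p)) -Inf else p$gain,
                    numeric(1))
    if (all(!is.finite(gains)) || max(gains) <= penalty) break
    j <- which.max(gains)
    k <- props[[j]]$k
    se <- segments[[j]]
    found_pos <- c(found_pos, k)
    found_gain <- c(found_gain, gains[j])
    segments[[j]] <- NULL
    segments <- c(segments, list(c(se[1], k), c(k + 1L, se[2])))
  }
  ord <- order(found_pos)
  .new_cpt_result("binseg", years[found_pos[ord] + 1L], found_gain[ord], NULL,
                  list(max_changes = max_changes, min_segment = min_segment,
                       penalty = penalty))
}

#' Consensus change points from the Bayesian and binseg candidates
#'
#' Applies the agreement rule: a consensus change exists where a Bayesian
#' candidate and a binseg candidate fall within `tolerance` years of each
#' other (the deterministic binseg year is reported). Matching is greedy,
#' one-to-one, in ascending year order; unmatched candidates from either
#' method are discarded. Consensus years closer together than `min_gap` are
#' thinned by keeping the year with the higher Bayesian posterior, and the
#' surviving years tile `year_range` into quasi-stable periods.
#'
#' @param bayes A `cpt_result` from [bcp_posterior()].
#' @param binseg A `cpt_result` from [binseg_changepoints()].
#' @param tolerance Maximum year difference for agreement (default 1).
#' @param min_gap Minimum years between consecutive change points (default 5).
#' @param year_range Length-2 integer vector, the observed year span.
#' @return A `consensus_cpts` list with `change_years`, `periods` (tibble of
#'   inclusive start/end years) and `provenance` (matched candidate pairs).
#' @export
consensus_changepoints <- function(bayes, binseg, tolerance = 1L,
                                   min_gap = 5L, year_range) {
  if (tolerance < 0 || min_gap < 1) {
    abort("tolerance must be >= 0 and min_gap >= 1",
          class = "fishshift_input_error")
  }
  year_range <- as.integer(range(year_range))
  b_years <- bayes$candidate_years
  b_scores <- bayes$scores
  s_years <- binseg$candidate_years
  used <- rep(FALSE, length(b_years))
  matches <- list()
  for (y in sort(s_years)) {
    d <- abs(b_years - y)
    d[used] <- Inf
    if (length(d) > 0 && min(d) <= tolerance) {
      j <- which.min(d) # ties resolve to the earlier Bayesian year
      used[j] <- TRUE
      matches[[length(matches) + 1]] <- tibble(
        change_year = as.integer(y), binseg_year = as.integer(y),
        bayes_year = b_years[j], bayes_posterior = b_scores[j]
      )
    }
  }
  prov <- if (length(matches) > 0) bind_rows(matches) else
    tibble(change_year = integer(0), binseg_year = integer(0),
           bayes_year = integer(0), bayes_posterior = numeric(0))
  prov <- prov[order(prov$change_year), ]
  # enforce the minimum gap: of two neighbours too close, keep the one whose
  # Bayesian posterior is higher
  while (nrow(prov) > 1 && any(diff(prov$change_year) < min_gap)) {
    i <- which(diff(prov$change_year) < min_gap)[1]
    drop <- if (prov$bayes_posterior[i] >= prov$bayes_posterior[i + 1]) i + 1 else i
    prov <- prov[-drop, ]
  }
  ch <- prov$change_year
  ch <- ch[ch > year_range[1] & ch <= year_range[2]]
  starts <- c(year_range[1], ch)
  ends <- c(ch - 1L, year_range[2])
  structure(list(
    change_years = as.integer(ch),
    periods = tibble(start_year = as.integer(starts), end_year = as.integer(ends)),
    provenance = prov,
    params = list(tolerance = tolerance, min_gap = min_gap,
                  year_range = year_range)
  ), class = "consensus_cpts")
}

#' @export
print.consensus_cpts <- function(x, ...) {
  cat("<consensus_cpts>\n")
  if (length(x$change_years) == 0) {
    cat("  no consensus change years; one period",
        paste(x$params$year_range, collapse = "-"), "\n")
  } else {
    cat("  change years:", paste(x$change_years, collapse = ", "), "\n")
    cat("  periods:",
        paste(sprintf("%d-%d", x$periods$start_year, x$periods$end_year),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run both change-point detectors and the consensus rule on a stock
#'
#' Convenience wrapper for the first regime-shift flag: runs
#' [bcp_posterior()] and [binseg_changepoints()] on the SSB series (missing
#' years are not allowed) and combines them with [consensus_changepoints()].
#'
#' @param series A [stock_series()].
#' @param tolerance,min_gap Consensus parameters.
#' @param seed Seed passed to the Bayesian sampler.
#' @param ... Further arguments to [bcp_posterior()] / [binseg_changepoints()].
#' @return A `consensus_cpts` with the two raw `cpt_result`s attached as
#'   `bayes` and `binseg`.
#' @export
detect_ssb_changepoints <- function(series, tolerance = 1L, min_gap = 5L,
                                    seed = NULL, ...) {
  validate_stock_series(series)
  ok <- !is.na(series$ssb)
  vals <- series$ssb[ok]
  yrs <- series$year[ok]
  bayes <- bcp_posterior(vals, yrs, seed = seed)
  bs <- binseg_changepoints(vals, yrs, min_segment = min_gap, ...)
  out <- consensus_changepoints(bayes, bs, tolerance = tolerance,
                                min_gap = min_gap, year_range = range(yrs))
  out$bayes <- bayes
  out$binseg <- bs
  out
}
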