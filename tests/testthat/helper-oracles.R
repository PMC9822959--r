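# Brute-force oracles used by the derived-value tests. These stay independent
# of the implementation paths they check: plain enumeration and grid search.

# all segmentations of 1..n into (m + 1) segments of length >= min_seg,
# minimising total within-segment sum of squared deviations from the mean
bf_mean_segmentation <- function(values, m, min_seg) {
  n <- length(values)
  sse <- function(v) sum((v - mean(v))^2)
  if (m == 0) return(list(splits = integer(0), sse = sse(values)))
  splits <- utils::combn(seq_len(n - 1), m, simplify = FALSE)
  best <- NULL
  for (sp in splits) {
    bounds <- c(0, sp, n)
    lens <- diff(bounds)
    if (any(lens < min_seg)) next
    tot <- sum(vapply(seq_len(m + 1), function(i) {
      sse(values[(bounds[i] + 1):bounds[i + 1]])
    }, numeric(1)))
    if (is.null(best) || tot < best$sse) best <- list(splits = sp, sse = tot)
  }
  best
}

# same, for per-segment OLS of y on x (intercept-only when x is constant)
bf_ols_segmentation <- function(x, y, m, min_seg) {
  n <- length(y)
  seg_rss <- function(i, j) {
    xs <- x[i:j]; ys <- y[i:j]
    if (stats::sd(xs) == 0) return(sum((ys - mean(ys))^2))
    sum(stats::resid(stats::lm(ys ~ xs))^2)
  }
  if (m == 0) return(list(splits = integer(0), rss = seg_rss(1, n)))
  splits <- utils::combn(seq_len(n - 1), m, simplify = FALSE)
  best <- NULL
  for (sp in splits) {
    bounds <- c(0, sp, n)
    if (any(diff(bounds) < min_seg)) next
    tot <- sum(vapply(seq_len(m + 1), function(i) {
      seg_rss(bounds[i] + 1, bounds[i + 1])
    }, numeric(1)))
    if (is.null(best) || tot < best$rss) best <- list(splits = sp, rss = tot)
  }
  best
}

# exhaustive psi-grid minimiser of broken-stick RSS (gaussian, one break)
grid_psi_rss <- function(s, r, n_grid = 1000) {
  grid <- seq(min(s), max(s), length.out = n_grid + 2)[-c(1, n_grid + 2)]
  rss <- vapply(grid, function(psi) {
    U <- pmax(s - psi, 0)
    sum(stats::resid(stats::lm(r ~ s + U))^2)
  }, numeric(1))
  list(psi = grid[which.min(rss)], step = diff(grid[1:2]), rss = min(rss))
}

# small CSV fixtures written on the fly
write_stock_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
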