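test_that("binary segmentation finds no change in a constant series", {
  bs <- binseg_changepoints(rep(100, 20))
  expect_length(bs$candidate_years, 0)
})

test_that("a clean step is split at the first index of the new segment", {
  v <- c(rep(100, 10), rep(200, 10))
  bs <- binseg_changepoints(v, min_segment = 5)
  expect_equal(bs$candidate_years, 11L)
})

test_that("two clean steps match the exhaustive two-split SSE oracle", {
  v <- c(rep(100, 10), rep(200, 10), rep(50, 10))
  bs <- binseg_changepoints(v, min_segment = 5)
  expect_equal(bs$candidate_years, c(11L, 21L))
  oracle <- bf_mean_segmentation(v, 2, 5)
  expect_equal(sort(bs$candidate_years - 1L), oracle$splits)
})

test_that("a single split equals the global argmax of the cost reduction", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(20:60, 1)
    v <- rnorm(n, rep(c(0, sample(1:4, 1)), c(floor(n / 2), ceiling(n / 2))))
    bs <- binseg_changepoints(v, max_changes = 1, min_segment = 3,
                              penalty = -Inf)
    oracle <- bf_mean_segmentation(v, 1, 3)
    expect_equal(bs$candidate_years - 1L, oracle$splits)
  }
})

test_that("binseg candidates are invariant to location and positive scale", {
  set.seed(42)
  v <- c(rnorm(12, 0), rnorm(12, 4), rnorm(12, -3))
  base <- binseg_changepoints(v, min_segment = 5)
  shifted <- binseg_changepoints(v + 1000, min_segment = 5)
  scaled <- binseg_changepoints(v * 37.5, min_segment = 5)
  expect_equal(shifted$candidate_years, base$candidate_years)
  expect_equal(scaled$candidate_years, base$candidate_years)
  expect_equal(scaled$scores, base$scores, tolerance = 1e-10)
})

test_that("the Gibbs sampler concentrates posterior mass on a true step", {
  set.seed(2)
  v <- c(rnorm(15, 100, 5), rnorm(15, 200, 5))
  bc <- bcp_posterior(v, seed = 99)
  tr <- bc$posterior_trace
  peak <- which.max(tr$prob)
  expect_equal(peak, 15L) # first year of the new period is position 16
  expect_gte(tr$prob[peak], 0.9)
  expect_gte(tr$prob[peak], 5 * max(tr$prob[-peak]))
})

test_that("the sampler is deterministic given a seed and quiet on constants", {
  set.seed(5)
  v <- rnorm(25, 50, 3)
  a <- bcp_posterior(v, seed = 7)
  b <- bcp_posterior(v, seed = 7)
  expect_identical(a$posterior_trace, b$posterior_trace)

  expect_warning(z <- bcp_posterior(rep(3, 30), seed = 1),
                 regexp = "zero variance")
  expect_true(all(z$posterior_trace$prob == 0))
  expect_lt(max(z$posterior_trace$prob), 0.5)
})

test_that("consensus follows the agreement, reporting and retention rules", {
  mk <- function(method, years, scores) {
    structure(list(method = method, candidate_years = as.integer(years),
                   scores = scores, posterior_trace = NULL, params = list()),
              class = "cpt_result")
  }
  # exact agreement (two-period structure)
  cc <- consensus_changepoints(mk("bayesian", 2002, 0.95),
                               mk("binseg", 2002, 10),
                               year_range = c(1965, 2021))
  expect_equal(cc$change_years, 2002L)
  expect_equal(cc$periods$start_year, c(1965L, 2002L))
  expect_equal(cc$periods$end_year, c(2001L, 2021L))

  # disagreement within tolerance resolves to the binseg year
  cc2 <- consensus_changepoints(mk("bayesian", 2003, 0.8),
                                mk("binseg", 2002, 9), tolerance = 1,
                                year_range = c(1990, 2020))
  expect_equal(cc2$change_years, 2002L)

  # min-gap retention keeps the higher posterior (enumerated-choice oracle)
  cc3 <- consensus_changepoints(mk("bayesian", c(1990, 1993), c(0.9, 0.6)),
                                mk("binseg", c(1990, 1993), c(9, 8)),
                                min_gap = 5, year_range = c(1980, 2000))
  expect_equal(cc3$change_years, 1990L)

  # beyond tolerance: no consensus, one period
  cc4 <- consensus_changepoints(mk("bayesian", 1995, 0.9),
                                mk("binseg", 2000, 9), tolerance = 1,
                                year_range = c(1980, 2010))
  expect_length(cc4$change_years, 0)
  expect_equal(nrow(cc4$periods), 1)
})

test_that("periods always tile the full year range", {
  for (seed in 1:10) {
    sim <- simulate_stepped_series(c(100, 180, 60), c(10, 12, 9),
                                   noise_sd = 8, seed = seed)
    cc <- detect_ssb_changepoints(
      stock_series(sim$year, pmax(sim$value, 1), rep(1, nrow(sim)),
                   rep(0.1, nrow(sim))), seed = seed)
    spans <- cc$periods$end_year - cc$periods$start_year + 1
    expect_equal(sum(spans), nrow(sim))
    expect_equal(cc$periods$start_year[1], min(sim$year))
    expect_equal(cc$periods$end_year[nrow(cc$periods)], max(sim$year))
    if (nrow(cc$periods) > 1) {
      expect_true(all(diff(cc$change_years) >= 5))
      expect_equal(cc$periods$start_year[-1] - 1, cc$periods$end_year[-nrow(cc$periods)])
    }
  }
})
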