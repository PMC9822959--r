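test_that("cross-correlation lag selection recovers constructed lags", {
  set.seed(1)
  f <- as.numeric(arima.sim(list(ar = 0.8), 40, sd = 0.1)) + 0.5
  expect_equal(select_lag(f, -f, max_lag = 5)$lag, 0L)
  expect_equal(select_lag(f, -f, max_lag = 5)$correlation, -1)

  ssb <- 1000 - 500 * dplyr::lag(f, 3)
  sel <- select_lag(f, ssb, max_lag = 8)
  expect_equal(sel$lag, 3L)

  expect_error(select_lag(rep(0.3, 40), rnorm(40)),
               class = "fishshift_input_error")
})

test_that("noisy lag recovery succeeds in at least 95% of 500 replicates", {
  hit <- 0
  for (i in 1:500) {
    set.seed(i)
    f <- as.numeric(arima.sim(list(ar = 0.8), 60, sd = 0.1)) + 0.5
    ssb <- 1000 - 500 * dplyr::lag(f, 5)
    ssb <- ssb + rnorm(60, 0, 0.05 * diff(range(ssb, na.rm = TRUE)))
    hit <- hit + (select_lag(f, ssb, max_lag = 10)$lag == 5L)
  }
  expect_gte(hit / 500, 0.95)
})

test_that("a stable linear relation yields zero structural breaks", {
  x <- seq(0, 3, length.out = 30)
  fit <- baiperron_breakpoints(x, 2 * x + 1)
  expect_equal(fit$n_breaks, 0L)
  expect_equal(fit$segment_coefficients$slope, 2, tolerance = 1e-10)
})

test_that("an exact slope change is located precisely", {
  x <- c(seq(1, 15), seq(1, 15))
  y <- c(2 * seq(1, 15), 30 - 2 * seq(1, 15))
  fit <- baiperron_breakpoints(x, y, max_breaks = 2)
  expect_equal(fit$n_breaks, 1L)
  expect_equal(fit$break_indices, 15L)
  expect_equal(fit$segment_coefficients$slope, c(2, -2), tolerance = 1e-9)
})

test_that("the DP minimum equals exhaustive enumeration on noisy data", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- runif(24, 0, 10)
    y <- c(1 + 2 * x[1:8], 20 - x[9:16], 5 + 0.5 * x[17:24]) + rnorm(24, 0, 1)
    fit <- baiperron_breakpoints(x, y, max_breaks = 2,
                                 min_segment_fraction = 0.15)
    min_seg <- fit$min_segment
    for (m in 0:2) {
      oracle <- bf_ols_segmentation(x, y, m, min_seg)
      expect_equal(fit$information_criterion$rss[m + 1], oracle$rss,
                   tolerance = 1e-8)
    }
  }
})

test_that("RSS is non-increasing in the number of breaks", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- runif(30)
    y <- rnorm(30, 2 * x)
    fit <- baiperron_breakpoints(x, y, max_breaks = 3,
                                 min_segment_fraction = 0.1)
    expect_true(all(diff(fit$information_criterion$rss) <= 1e-10))
  }
})

test_that("constant fishing mortality falls back to flagged intercept fits", {
  st <- stock_series(1981:2010, 1000 + 100 * sin(1:30), rep(10, 30),
                     rep(0.3, 30))
  fit <- fit_fssb_breakpoints(st, lag = 0)
  expect_true(all(fit$segment_coefficients$intercept_only))
})

test_that("a collapsed F-SSB relation shows a final decoupled phase", {
  st <- loop_scenario("open", seed = 5)
  fit <- fit_fssb_breakpoints(st, lag = 0)
  expect_gte(fit$n_breaks, 1)
  final_slope <- fit$segment_coefficients$slope[fit$n_breaks + 1]
  first_slope <- fit$segment_coefficients$slope[1]
  expect_lt(first_slope, 0) # pressure depresses biomass before collapse
  expect_lt(abs(final_slope), abs(first_slope) / 4)
})

test_that("reversible dynamics never classify as a loop", {
  for (seed in 1:25) {
    cls <- classify_hysteresis(loop_scenario("reversible", seed = seed))
    expect_equal(cls$classification, "none")
  }
})

test_that("fold dynamics classify as closed or open loops as constructed", {
  cl <- classify_hysteresis(loop_scenario("closed", seed = 3))
  expect_equal(cl$classification, "closed_loop")
  tr <- sim_truth(loop_scenario("closed", seed = 3))
  expect_lt(tr$recovery_F, tr$collapse_F)

  op <- classify_hysteresis(loop_scenario("open", seed = 3))
  expect_equal(op$classification, "open_loop")
  expect_lt(op$final_ssb, op$pre_collapse_min)
  expect_lte(op$final_f, op$f_sustain)
})

test_that("monotone pressure is reported instead of a loop verdict", {
  n <- 40
  st <- simulate_hysteretic_stock(seq(0, 0.3, length.out = n), allee_A = 0,
                                  process_sd = 0.02, seed = 9)
  cls <- classify_hysteresis(st, lag = 0)
  expect_equal(cls$classification, "none")
  expect_match(cls$reason, "monotone")
})
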