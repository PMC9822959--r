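test_that("stepped series equal the step function without noise and are
           reproducible with it", {
  sim <- simulate_stepped_series(c(10, 20), c(5, 6))
  expect_equal(sim$value, rep(c(10, 20), c(5, 6)))
  expect_equal(sim_truth(sim)$true_change_years, 1965L)

  a <- simulate_stepped_series(c(1, 2), c(10, 10), noise_sd = 1, seed = 3)
  b <- simulate_stepped_series(c(1, 2), c(10, 10), noise_sd = 1, seed = 3)
  expect_identical(a$value, b$value)
})

test_that("AR(1) noise reproduces its lag-1 autocorrelation", {
  sim <- simulate_stepped_series(0, 10000, noise_sd = 1, ar1_rho = 0.55,
                                 seed = 42)
  rho_hat <- acf(sim$value, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(rho_hat - 0.55), 0.03)
})

test_that("an unfished stock stays at carrying capacity", {
  st <- simulate_hysteretic_stock(rep(0, 30), b0 = 1e5, K = 1e5)
  expect_equal(st$ssb, rep(1e5, 30), tolerance = 1e-12)
})

test_that("the reversible limit retraces its equilibrium path exactly", {
  f_lv <- seq(0, 0.4, by = 0.1)
  dwell <- 80
  fp <- rep(c(f_lv, rev(f_lv)), each = dwell)
  st <- simulate_hysteretic_stock(fp, allee_A = 0, process_sd = 0)
  up <- st$ssb[seq_along(f_lv) * dwell]
  dn <- rev(st$ssb[length(f_lv) * dwell + seq_along(f_lv) * dwell])
  expect_lt(max(abs(up - dn)), 1e-9 * max(up))
})

test_that("the fold truth orders collapse and recovery levels correctly", {
  for (aA in c(0.1, 0.2, 0.3)) {
    tr <- sim_truth(simulate_hysteretic_stock(rep(0, 5), allee_A = aA * 1e5))
    expect_lt(tr$recovery_F, tr$collapse_F)
    expect_gt(tr$recovery_F, 0)
  }
})

test_that("collapse and recovery honour the continuation oracle", {
  tr0 <- sim_truth(simulate_hysteretic_stock(rep(0, 5)))
  ramp <- seq(0, 1.2 * tr0$collapse_F, length.out = 60)
  st <- simulate_hysteretic_stock(c(ramp, rep(max(ramp), 25)), process_sd = 0)
  floor <- sim_truth(st)$floor
  # no collapse while F stays below the fold
  below <- which(ramp < tr0$collapse_F - diff(ramp[1:2]))
  expect_true(all(st$ssb[below] > 5 * floor))
  # collapse completes once F dwells beyond the fold
  expect_lte(min(st$ssb), 1.01 * floor)
  # held just above recovery_F the stock stays down; just below, it escapes
  n_hold <- 80
  stay <- simulate_hysteretic_stock(
    c(ramp, rep(max(ramp), 25), rep(1.1 * tr0$recovery_F, n_hold)),
    process_sd = 0)
  expect_lt(stay$ssb[length(stay$ssb)], 2 * floor)
  go <- simulate_hysteretic_stock(
    c(ramp, rep(max(ramp), 25), rep(0.9 * tr0$recovery_F, n_hold)),
    process_sd = 0)
  expect_gt(go$ssb[nrow(go)], 10 * floor)
})

test_that("regime-dependent Ricker data follow the exact curve when quiet", {
  s <- seq(100, 1000, length.out = 20)
  d <- simulate_srr_regimes(1.4, 1e-3, 1961L, s_path = s)
  expect_equal(d$r, s * exp(1.4 - 1e-3 * s), tolerance = 1e-12)

  a <- simulate_srr_regimes(c(1, 2), c(1e-3, 2e-3), c(1961L, 1975L), n = 30,
                            lognorm_sd = 0.2, seed = 4)
  b <- simulate_srr_regimes(c(1, 2), c(1e-3, 2e-3), c(1961L, 1975L), n = 30,
                            lognorm_sd = 0.2, seed = 4)
  expect_identical(a$r, b$r)
})

test_that("generated stocks satisfy the stock-series invariants", {
  for (seed in 1:5) {
    st <- simulate_hysteretic_stock(f_path_ramp(0.4, 0.1), process_sd = 0.05,
                                    seed = seed)
    expect_silent(validate_stock_series(st))
    expect_true(all(st$ssb > 0))
    expect_true(all(st$recruitment > 0))
  }
})

test_that("threshold generator plants the recorded SST threshold", {
  sim <- simulate_sst_threshold_srr(threshold = 11, seed = 2)
  tr <- sim_truth(sim)
  expect_equal(tr$true_sst_threshold, 11)
  cold <- sim$env$sst < 11
  d <- merge(sim$srr, sim$env, by = "year")
  fit_c <- lm(r ~ s, data = d[d$sst < 11, ])
  fit_w <- lm(r ~ s, data = d[d$sst >= 11, ])
  expect_gt(coef(fit_c)[2], 3 * coef(fit_w)[2])
})
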