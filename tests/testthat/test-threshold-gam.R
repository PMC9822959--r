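test_that("the penalized spline reaches the OLS line on linear data", {
  set.seed(3)
  x <- sort(runif(50, 0, 10))
  y <- 2 + 0.5 * x
  g <- fit_pspline_gam(x, y, k = 4)
  expect_lt(abs(g$edf - 1), 0.1)
  ols <- fitted(lm(y ~ x))
  expect_lt(max(abs(g$fitted - ols)[x > 1 & x < 9]), 1e-6)
})

test_that("reported GCV satisfies its defining formula", {
  set.seed(4)
  x <- sort(runif(40, 0, 10))
  y <- sin(x) + rnorm(40, 0, 0.3)
  for (k in c(3, 4, 8)) {
    g <- fit_pspline_gam(x, y, k = k)
    n <- length(y)
    rss <- sum((y - g$fitted)^2)
    expect_equal(g$gcv, n * rss / (n - g$edf_total)^2, tolerance = 1e-10)
    expect_gte(g$edf, 1 - 1e-6)
    expect_lte(g$edf, k - 1 + 1e-6)
  }
})

test_that("grid selection matches a ten-fold denser lambda grid", {
  set.seed(5)
  x <- sort(runif(60, 0, 10))
  y <- sin(x) + rnorm(60, 0, 0.3)
  coarse <- 10^seq(-4, 8, by = 0.25)
  dense <- 10^seq(-4, 8, by = 0.025)
  g1 <- fit_pspline_gam(x, y, k = 8, lambda_grid = coarse)
  g2 <- fit_pspline_gam(x, y, k = 8, lambda_grid = dense)
  # the coarse-grid optimum sits within one coarse step of the dense optimum
  expect_lte(abs(log10(g1$lambda) - log10(g2$lambda)), 0.25 + 1e-9)
})

test_that("the smoother agrees with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  set.seed(6)
  x <- sort(runif(80, 0, 10))
  y <- sin(x) + 0.2 * x + rnorm(80, 0, 0.25)
  ours <- fit_pspline_gam(x, y, k = 10)
  ref <- mgcv::gam(y ~ s(x, k = 10, bs = "ps"))
  expect_gt(cor(ours$fitted, fitted(ref)), 0.99)
  expect_lt(sqrt(mean((ours$fitted - fitted(ref))^2)) / sd(y), 0.15)
})

test_that("input contracts of the spline fitter are enforced", {
  expect_error(fit_pspline_gam(1:4, 1:4, k = 3),
               class = "fishshift_input_error")
  expect_error(fit_pspline_gam(rep(1, 20), rnorm(20)),
               class = "fishshift_degenerate_error")
  expect_error(fit_pspline_gam(1:20, rnorm(20), k = 2),
               class = "fishshift_input_error")
})

test_that("the planted SST threshold is recovered within one grid step", {
  sim <- simulate_sst_threshold_srr(seed = 11)
  fit <- fit_threshold_gam(sim$srr, sim$env)
  step <- diff(fit$gcv_profile$threshold[1:2])
  expect_lte(abs(fit$threshold - sim_truth(sim)$true_sst_threshold), step)
  # the reported threshold attains the profile minimum
  expect_equal(fit$gcv, min(fit$gcv_profile$gcv, na.rm = TRUE))
})

test_that("noiseless linear regimes have edf within 0.1 of 1", {
  sim <- simulate_sst_threshold_srr(threshold = 12, noise_sd = 0, n = 60,
                                    seed = 13)
  fit <- fit_threshold_gam(sim$srr, sim$env)
  expect_lt(abs(fit$edf_below - 1), 0.1)
  expect_lt(abs(fit$edf_above - 1), 0.1)
})

test_that("LOOCV prefers the threshold model only when a threshold exists", {
  pref_alt <- pref_null <- 0
  for (seed in 1:5) {
    alt <- simulate_sst_threshold_srr(seed = 20 + seed)
    pref_alt <- pref_alt + loocv_tgam_vs_gam(alt$srr, alt$env)$prefers_tgam
    nul <- simulate_sst_threshold_srr(slope_below = 2, slope_above = 2,
                                      seed = 40 + seed)
    pref_null <- pref_null + loocv_tgam_vs_gam(nul$srr, nul$env)$prefers_tgam
  }
  expect_gte(pref_alt, 4)
  expect_lte(pref_null, 2)
})

test_that("the three-criteria decision rule composes as stated", {
  fake_fit <- structure(list(
    threshold = 10.5, edf_below = 1.2, edf_above = 2.6,
    slope_p_below = 0.001, slope_p_above = 0.3,
    gcv_profile = tibble::tibble(threshold = 1:10,
                                 gcv = c(5, rep(10, 9))),
    resid_acf1 = 0.1
  ), class = "tgam_fit")
  dec <- evaluate_threshold_criteria(fake_fit, loocv = TRUE)
  expect_equal(dec$verdict, "accepted")
  expect_equal(dec$threshold, 10.5)

  flat <- fake_fit
  flat$edf_below <- 1; flat$edf_above <- 1
  flat$slope_p_below <- 0.4; flat$slope_p_above <- 0.4
  flat$gcv_profile <- tibble::tibble(threshold = 1:10, gcv = rep(10, 10))
  dec0 <- evaluate_threshold_criteria(flat, loocv = FALSE)
  expect_equal(dec0$verdict, "rejected")
  expect_false(any(unlist(dec0$criteria)))

  # LOOCV preference alone is never sufficient
  dec1 <- evaluate_threshold_criteria(flat, loocv = TRUE)
  expect_equal(dec1$verdict, "rejected")
})

test_that("edf interpretation bands follow the convention", {
  expect_equal(fishshift:::.edf_band(1), "linear")
  expect_equal(fishshift:::.edf_band(1.7), "weakly non-linear")
  expect_equal(fishshift:::.edf_band(2.4), "strongly non-linear")
})
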