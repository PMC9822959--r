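test_that("Beverton-Holt recovers exact parameters from noiseless data", {
  s <- seq(100, 2000, length.out = 40)
  fit <- fit_beverton_holt(srr_data(1:40, s, 2 * s / (1 + 0.001 * s)))
  expect_equal(fit$alpha, 2, tolerance = 1e-6)
  expect_equal(fit$beta, 0.001, tolerance = 1e-6)

  # beta = 0 limit: regression through the origin on the log scale
  fit0 <- fit_beverton_holt(srr_data(1:40, s, 3 * s))
  expect_equal(fit0$alpha, 3, tolerance = 1e-8)
  expect_equal(fit0$beta, 0, tolerance = 1e-8)
})

test_that("Beverton-Holt matches an independent optimizer on noisy data", {
  diffs <- vapply(1:20, function(seed) {
    set.seed(seed)
    s <- runif(50, 100, 2000)
    r <- 2 * s / (1 + 0.001 * s) * exp(rnorm(50, 0, 0.3))
    fit <- fit_beverton_holt(srr_data(1:50, s, r))
    obj <- function(p) sum((log(r) - log(exp(p[1]) * s /
                                           (1 + exp(p[2]) * s)))^2)
    ref <- optim(c(log(2), log(0.001)), obj,
                 control = list(maxit = 5000, reltol = 1e-12))
    abs(fit$alpha - exp(ref$par[1])) / exp(ref$par[1])
  }, numeric(1))
  expect_lt(median(diffs), 0.01)
})

test_that("Ricker linearised fit equals the closed-form OLS solution", {
  s <- seq(100, 2000, length.out = 30)
  fit <- fit_ricker(srr_data(1:30, s, s * exp(1 - 0.002 * s)))
  expect_equal(fit$alpha, 1, tolerance = 1e-12)
  expect_equal(fit$beta, 0.002, tolerance = 1e-12)

  set.seed(4)
  s <- runif(40, 50, 1500)
  r <- s * exp(0.8 - 0.001 * s) * exp(rnorm(40, 0, 0.2))
  fit <- fit_ricker(srr_data(1:40, s, r))
  X <- cbind(1, s)
  beta_hat <- solve(t(X) %*% X, t(X) %*% log(r / s))
  expect_equal(fit$alpha, beta_hat[1], tolerance = 1e-10)
  expect_equal(-fit$beta, beta_hat[2], tolerance = 1e-10)

  up <- fit_ricker(srr_data(1:30, seq(100, 1000, length.out = 30),
                            seq(100, 1000, length.out = 30)^1.5))
  expect_lt(up$beta, 0)
  expect_match(paste(up$flags, collapse = " "), "non-dome")
})

test_that("linear and log-log fits reproduce exact relations", {
  s <- seq(10, 500, length.out = 25)
  lin <- fit_srr_linear(srr_data(1:25, s, 3 * s))
  expect_equal(lin$beta, 3, tolerance = 1e-10)
  expect_equal(lin$alpha, 0, tolerance = 1e-8)

  ll <- fit_srr_linear(srr_data(1:25, s, 2 * sqrt(s)), log_scale = TRUE)
  expect_equal(ll$beta, 0.5, tolerance = 1e-10)
  expect_equal(ll$alpha, log(2), tolerance = 1e-10)

  set.seed(2)
  r <- 3 * s + rnorm(25, 0, 10)
  f2 <- fit_srr_linear(srr_data(1:25, s, pmax(r, 1)))
  ref <- lm(pmax(r, 1) ~ s)
  expect_equal(sqrt(mean((f2$fitted - pmax(r, 1))^2)),
               sqrt(mean(resid(ref)^2)), tolerance = 1e-10)
})

test_that("GLM family choice follows the Pearson dispersion bands", {
  set.seed(10)
  s <- runif(100, 1, 10)
  r_pois <- rpois(100, 20)
  fc <- choose_glm_family(srr_data(1:100, s, pmax(r_pois, 1)))
  expect_equal(fc$family, "poisson")
  expect_true(fc$dispersion >= 0.8 && fc$dispersion <= 1.2)

  set.seed(11)
  r_nb <- rnbinom(100, size = 0.5, mu = 50)
  fc2 <- choose_glm_family(srr_data(1:100, s, pmax(r_nb, 1)))
  expect_equal(fc2$family, "negative_binomial")

  # hand-computed dispersion on a tiny table
  d <- srr_data(1:10, rep(c(1, 2), 5), rep(c(4, 6), 5))
  fit <- suppressWarnings(glm(r ~ s, data = d, family = quasipoisson()))
  phi_hand <- sum((d$r - fitted(fit))^2 / fitted(fit)) / (10 - 2)
  expect_equal(choose_glm_family(d)$dispersion, phi_hand, tolerance = 1e-10)

  expect_equal(choose_glm_family(d, rescaled = TRUE)$family, "gaussian")
})

test_that("segmented fit recovers a noiseless breakpoint to high precision", {
  set.seed(1)
  s <- runif(60, 100, 1000)
  r <- ifelse(s < 500, s, 500 - 0.5 * (s - 500))
  fit <- fit_segmented_glm(srr_data(1:60, s, pmax(r, 1)))
  expect_equal(fit$psi, 500, tolerance = 1e-3)
  expect_equal(fit$segment_params$slope, c(1, -0.5), tolerance = 1e-6)
})

test_that("segmented psi agrees with an exhaustive grid search under noise", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    s <- runif(60, 100, 1000)
    r <- ifelse(s < 480, 1.2 * s, 1.2 * 480 + 0.2 * (s - 480)) +
      rnorm(60, 0, 30)
    d <- srr_data(1:60, s, pmax(r, 1))
    fit <- fit_segmented_glm(d)
    oracle <- grid_psi_rss(d$s, d$r)
    hits <- hits + (abs(fit$psi - oracle$psi) <= oracle$step)
  }
  expect_gte(hits, 18)
})

test_that("straight-line data yields an unsupported break", {
  set.seed(3)
  s <- runif(50, 100, 1000)
  r <- 0.8 * s + rnorm(50, 0, 25)
  fit <- fit_segmented_glm(srr_data(1:50, s, pmax(r, 1)))
  expect_match(paste(fit$flags, collapse = " "), "no supported break")
})

test_that("LOOCV errors are exact on noiseless linear data", {
  s <- seq(10, 100, length.out = 12)
  cmp <- loocv_compare(srr_data(1:12, s, 2 * s), candidates = "linear")
  expect_equal(cmp$table$rmse_train, 0, tolerance = 1e-9)
  expect_equal(cmp$table$rmse_test, 0, tolerance = 1e-9)
})

test_that("linear LOOCV matches the hat-matrix identity", {
  set.seed(5)
  s <- runif(10, 10, 100)
  r <- pmax(3 * s + rnorm(10, 0, 8), 1)
  d <- srr_data(1:10, s, r)
  cmp <- loocv_compare(d, candidates = "linear")
  fit <- lm(r ~ s, data = d)
  h <- lm.influence(fit)$hat
  loo <- resid(fit) / (1 - h)
  expect_equal(cmp$table$rmse_test, sqrt(mean(loo^2)), tolerance = 1e-8)
})

test_that("temporal SRR breakpoints recover exact regime changes", {
  set.seed(6)
  s <- runif(45, 100, 1500)
  d <- simulate_srr_regimes(c(1.5, 0.7, 1.8), c(2e-3, 2e-3, 1e-3),
                            c(1960L, 1975L, 1990L), s_path = s)
  fit <- fit_srr_breakpoints(d)
  expect_equal(fit$bp$n_breaks, 2L)
  expect_equal(fit$break_years, c(1975L, 1990L))

  # stationary data: no temporal break
  d0 <- simulate_srr_regimes(1.2, 2e-3, 1960L, n = 40, lognorm_sd = 0.15,
                             seed = 8)
  fit0 <- fit_srr_breakpoints(d0)
  expect_equal(fit0$bp$n_breaks, 0L)
})

test_that("a halved-productivity break year is recovered within two years", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    s <- runif(50, 100, 1500)
    d <- simulate_srr_regimes(c(2, 1), c(1.5e-3, 1.5e-3), c(1961L, 1986L),
                              s_path = s, lognorm_sd = 0.15)
    fit <- fit_srr_breakpoints(d, max_breaks = 2)
    hits <- hits + (fit$bp$n_breaks >= 1 &&
                      min(abs(fit$break_years - 1986)) <= 2)
  }
  expect_gte(hits / 100, 0.9)
})

test_that("predictions from every model kind are non-negative", {
  set.seed(9)
  s <- runif(30, 100, 1500)
  d <- srr_data(1:30, s, pmax(0.5 * s + rnorm(30, 0, 100), 1))
  for (kind in c("linear", "loglog_linear", "ricker", "beverton_holt")) {
    fit <- fishshift:::.fit_srr_kind(d, kind)
    expect_true(all(predict_srr(fit, c(1, 500, 5000)) >= 0), info = kind)
  }
})
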