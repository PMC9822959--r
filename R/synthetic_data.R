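#' Extract the simulation truth attached to a generated dataset
#'
#' Every generator in the package records its ground truth (planted change
#' years, bifurcation levels, regime parameters, thresholds, seed) as an
#' attribute of the returned data so recovery can be scored without side
#' channels.
#'
#' @param x An object returned by one of the `simulate_*()` generators.
#' @return A named list of true parameter values.
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Simulate a piecewise-quasi-stable series with abrupt mean shifts
#'
#' Emulates an SSB trajectory made of quasi-stable periods: a piecewise
#' constant mean plus stationary AR(1) Gaussian noise. The truth records the
#' first year of every period after the first, i.e. the planted change years.
#'
#' @param segment_means Mean level per period.
#' @param segment_lengths Length (years) per period; each at least 5, honouring
#'   the five-year quasi-stability rule.
#' @param noise_sd Marginal standard deviation of the noise.
#' @param ar1_rho Lag-1 autocorrelation of the noise, in (-1, 1).
#' @param start_year First calendar year.
#' @param seed Optional integer seed; fixed seed implies bit-identical output.
#' @return A tibble with columns `year` and `value`, truth in [sim_truth()].
#' @export
simulate_stepped_series <- function(segment_means, segment_lengths,
                                    noise_sd = 0, ar1_rho = 0,
                                    start_year = 1960L, seed = NULL) {
  if (length(segment_means) != length(segment_lengths)) {
    abort("segment_means and segment_lengths must have equal length",
          class = "fishshift_input_error")
  }
  if (any(segment_lengths < 5)) {
    abort("every segment must span at least 5 years",
          class = "fishshift_input_error")
  }
  if (abs(ar1_rho) >= 1) {
    abort("ar1_rho must lie strictly inside (-1, 1)",
          class = "fishshift_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- sum(segment_lengths)
  mu <- rep(segment_means, segment_lengths)
  eps <- numeric(n)
  if (noise_sd > 0) {
    innov_sd <- noise_sd * sqrt(1 - ar1_rho^2)
    eps[1] <- rnorm(1, 0, noise_sd)
    if (n > 1) {
      innov <- rnorm(n - 1, 0, innov_sd)
      for (t in 2:n) eps[t] <- ar1_rho * eps[t - 1] + innov[t - 1]
    }
  }
  years <- start_year + seq_len(n) - 1L
  starts <- start_year + cumsum(segment_lengths) - segment_lengths
  out <- tibble(year = years, value = mu + eps)
  attr(out, "truth") <- list(
    true_change_years = as.integer(starts[-1]),
    segment_means = segment_means,
    segment_lengths = as.integer(segment_lengths),
    noise_sd = noise_sd, ar1_rho = ar1_rho, seed = seed
  )
  out
}

.percap_growth <- function(B, r_growth, K, allee_A) {
  dep <- if (allee_A > 0) B / (B + allee_A) else 1
  r_growth * dep * (1 - B / K)
}

.step_biomass <- function(B, f, r_growth, K, allee_A, floor) {
  pmax(floor, B + B * .percap_growth(B, r_growth, K, allee_A) - f * B)
}

.bifurcation_truth <- function(r_growth, K, allee_A, floor, f_grid_step) {
  f_grid <- seq(0, r_growth, by = f_grid_step)
  # upper-branch continuation: follow the equilibrium from B = K as F rises
  B_up <- rep(K, length(f_grid))
  for (i in seq_len(3000)) {
    B_up <- .step_biomass(B_up, f_grid, r_growth, K, allee_A, floor)
  }
  alive <- B_up > 2 * floor
  collapse_F <- if (any(!alive)) f_grid[max(which(alive))] else max(f_grid)
  # escape from the depleted floor state
  B_lo <- rep(floor, length(f_grid))
  for (i in seq_len(4000)) {
    B_lo <- .step_biomass(B_lo, f_grid, r_growth, K, allee_A, floor)
  }
  esc <- B_lo > pmax(2 * floor, allee_A)
  recovery_F <- if (any(esc)) f_grid[max(which(esc))] else 0
  list(collapse_F = collapse_F, recovery_F = min(recovery_F, collapse_F),
       f_grid_step = f_grid_step)
}

#' Simulate a harvested stock with fold-bifurcation hysteresis
#'
#' A depensatory (Holling-type) discrete logistic under harvesting:
#' \deqn{B_{t+1} = B_t + r B_t \frac{B_t}{B_t + A}\left(1 - \frac{B_t}{K}\right) - f_t B_t,}
#' multiplied by lognormal process noise and floored at a quasi-extinction
#' biomass. With `allee_A = 0` the depensation factor is 1 and the dynamics
#' reduce to the reversible logistic (no hysteresis). With `allee_A > 0` the
#' harvested system has a fold: the stock collapses when F exceeds
#' `collapse_F` and only escapes the depleted state once F falls below
#' `recovery_F < collapse_F`. Both levels are computed by numerical
#' equilibrium continuation of the noise-free map over an F grid and recorded
#' in the truth. Recruitment is emitted from a Ricker curve applied to
#' biomass.
#'
#' @param f_path Fishing mortality per year (per year); drives the scenario.
#' @param r_growth Intrinsic growth rate (per year).
#' @param K Carrying capacity (tonnes).
#' @param allee_A Depensation half-saturation biomass (tonnes); 0 disables it.
#' @param process_sd Standard deviation of the lognormal process noise (log
#'   scale).
#' @param b0 Initial biomass (tonnes).
#' @param floor_frac Quasi-extinction floor as a fraction of `K`.
#' @param srr_alpha,srr_beta Ricker parameters for the emitted recruitment.
#' @param recruitment_age Age at which the emitted recruitment is indexed.
#' @param start_year First calendar year.
#' @param seed Optional integer seed.
#' @param f_grid_step Resolution of the F grid used for the bifurcation truth.
#' @return A [stock_series()] with truth in [sim_truth()] (`collapse_F`,
#'   `recovery_F`, SRR parameters, floor, seed).
#' @export
simulate_hysteretic_stock <- function(f_path, r_growth = 0.9, K = 1e5,
                                      allee_A = 0.2 * K, process_sd = 0,
                                      b0 = K, floor_frac = 0.05,
                                      srr_alpha = 1, srr_beta = 1.2e-5,
                                      recruitment_age = 0L,
                                      start_year = 1960L, seed = NULL,
                                      f_grid_step = 1e-3) {
  if (any(f_path < 0)) {
    abort("f_path must be non-negative", class = "fishshift_input_error")
  }
  if (allee_A < 0 || allee_A >= K) {
    abort("allee_A must satisfy 0 <= allee_A < K",
          class = "fishshift_input_error")
  }
  floor <- floor_frac * K
  if (b0 <= floor || b0 > K) {
    abort("b0 must lie in (floor, K]", class = "fishshift_input_error")
  }
  # a positive unfished equilibrium must exist
  test_B <- K
  for (i in seq_len(500)) {
    test_B <- .step_biomass(test_B, 0, r_growth, K, allee_A, floor)
  }
  if (test_B <= 2 * floor) {
    abort("no positive equilibrium at F = 0 for these parameters",
          class = "fishshift_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(f_path)
  B <- numeric(n)
  B[1] <- b0
  noise <- if (process_sd > 0) exp(rnorm(n, 0, process_sd)) else rep(1, n)
  for (t in seq_len(n - 1)) {
    B[t + 1] <- max(floor,
                    .step_biomass(B[t], f_path[t], r_growth, K, allee_A,
                                  floor) * noise[t + 1])
  }
  rec <- B * exp(srr_alpha - srr_beta * B)
  series <- stock_series(
    years = start_year + seq_len(n) - 1L,
    ssb = B, recruitment = rec, fmort = f_path,
    stock_id = "synthetic-hysteretic", recruitment_age = recruitment_age
  )
  truth <- .bifurcation_truth(r_growth, K, allee_A, floor, f_grid_step)
  truth$true_srr_params <- c(alpha = srr_alpha, beta = srr_beta)
  truth$allee_A <- allee_A
  truth$floor <- floor
  truth$seed <- seed
  attr(series, "truth") <- truth
  series
}

#' Build a ramp-shaped fishing mortality path
#'
#' Linear ramp from `f_start` up to `f_max`, back down to `f_end`, then held.
#' Convenience for collapse/recovery scenarios.
#'
#' @param f_max Peak fishing mortality.
#' @param f_end Level after the down-ramp (the "floor" of the scenario).
#' @param up,down,hold Years spent ramping up, ramping down and holding at
#'   `f_end`.
#' @param peak_hold Years spent dwelling at `f_max` between the ramps (gives a
#'   stock beyond its fold point time to actually collapse).
#' @param f_start Initial level.
#' @return Numeric vector of length `up + peak_hold + down + hold`.
#' @export
f_path_ramp <- function(f_max, f_end = 0, up = 25L, down = 10L, hold = 25L,
                        peak_hold = 10L, f_start = 0) {
  c(seq(f_start, f_max, length.out = up),
    rep(f_max, peak_hold),
    seq(f_max, f_end, length.out = down + 1L)[-1L],
    rep(f_end, hold))
}

#' Simulate a stock-recruitment dataset with regime-dependent Ricker curves
#'
#' Recruitment follows \eqn{r_t = s_t e^{\alpha_j - \beta_j s_t}} with the
#' Ricker parameters switching at known regime start years, times lognormal
#' noise.
#'
#' @param alphas,betas Ricker parameters, one per regime.
#' @param regime_years Start year of each regime; the first is the first year
#'   of the series.
#' @param s_path Parent SSB per year (tonnes); its length sets the series
#'   length. If `NULL`, uniform draws over `s_range`.
#' @param n Series length when `s_path` is `NULL`.
#' @param s_range Range for uniform SSB draws.
#' @param lognorm_sd Standard deviation of the lognormal recruitment noise
#'   (log scale).
#' @param seed Optional integer seed.
#' @return An `srr_data` tibble with truth in [sim_truth()].
#' @export
simulate_srr_regimes <- function(alphas, betas, regime_years, s_path = NULL,
                                 n = 50L, s_range = c(100, 2000),
                                 lognorm_sd = 0, seed = NULL) {
  if (length(alphas) != length(betas) ||
      length(alphas) != length(regime_years)) {
    abort("alphas, betas and regime_years must have equal length",
          class = "fishshift_input_error")
  }
  if (any(alphas <= 0)) {
    abort("Ricker alphas must be positive", class = "fishshift_input_error")
  }
  if (is.unsorted(regime_years, strictly = TRUE)) {
    abort("regime_years must be strictly increasing",
          class = "fishshift_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(s_path)) s_path <- runif(n, s_range[1], s_range[2])
  n <- length(s_path)
  years <- regime_years[1] + seq_len(n) - 1L
  regime <- findInterval(years, regime_years)
  eps <- if (lognorm_sd > 0) exp(rnorm(n, 0, lognorm_sd)) else rep(1, n)
  r <- s_path * exp(alphas[regime] - betas[regime] * s_path) * eps
  out <- srr_data(years, s_path, r)
  attr(out, "truth") <- list(
    true_srr_params = data.frame(regime_start = regime_years,
                                 alpha = alphas, beta = betas),
    true_change_years = as.integer(regime_years[-1]),
    lognorm_sd = lognorm_sd, seed = seed
  )
  out
}

#' Simulate a stock-recruitment dataset with an SST threshold
#'
#' SST is uniform over `sst_range`; recruitment is linear in SSB with a slope
#' that switches at the planted SST threshold, plus Gaussian noise (floored
#' just above zero so pairs stay valid).
#'
#' @param threshold Planted SST threshold, degrees Celsius.
#' @param slope_below,slope_above Recruitment-per-SSB slopes in the cold and
#'   warm regimes.
#' @param sst_range Interval of SST values (degrees Celsius).
#' @param n Number of years (at least 30).
#' @param noise_sd Standard deviation of the additive recruitment noise.
#' @param s_range Range of uniform SSB draws (tonnes).
#' @param start_year First calendar year.
#' @param seed Optional integer seed.
#' @return A list with elements `srr` (an `srr_data` tibble) and `env` (an
#'   `env_series` tibble); truth in [sim_truth()] of the list.
#' @export
simulate_sst_threshold_srr <- function(threshold = 12, slope_below = 2,
                                       slope_above = 0.5,
                                       sst_range = c(8, 16), n = 60L,
                                       noise_sd = 50, s_range = c(200, 1000),
                                       start_year = 1960L, seed = NULL) {
  if (threshold <= sst_range[1] || threshold >= sst_range[2]) {
    abort("threshold must lie strictly inside sst_range",
          class = "fishshift_input_error")
  }
  if (n < 30) {
    abort("n must be at least 30", class = "fishshift_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  years <- start_year + seq_len(n) - 1L
  sst <- runif(n, sst_range[1], sst_range[2])
  s <- runif(n, s_range[1], s_range[2])
  slope <- ifelse(sst < threshold, slope_below, slope_above)
  r <- pmax(slope * s + rnorm(n, 0, noise_sd), 1)
  out <- list(srr = srr_data(years, s, r), env = env_series(years, sst))
  attr(out, "truth") <- list(
    true_sst_threshold = threshold,
    slope_below = slope_below, slope_above = slope_above,
    noise_sd = noise_sd, seed = seed
  )
  out
}

#' Canonical collapse/recovery scenarios for the loop classifier
#'
#' Three fixed fishing-mortality scenarios over the depensatory stock of
#' [simulate_hysteretic_stock()]: `"closed"` ramps F to 1.2x the collapse
#' level, dwells there long enough for the collapse to complete, then drops F
#' to 0.4x the recovery level so the stock escapes the depleted state;
#' `"open"` is identical except that F is only reduced to 1.5x the recovery
#' level, trapping the stock; `"reversible"` runs a comparable ramp on the
#' Allee-free (logistic) stock, which retraces its path. The truth object of
#' the returned series carries the oracle collapse and recovery levels.
#'
#' @param type One of `"closed"`, `"open"`, `"reversible"`.
#' @param seed Integer seed.
#' @param process_sd Lognormal process noise (log sd); defaults follow the
#'   scenario definitions (3% for the Allee runs, 5% for the reversible run).
#' @return A [stock_series()] with truth in [sim_truth()].
#' @export
loop_scenario <- function(type = c("closed", "open", "reversible"),
                          seed = NULL, process_sd = NULL) {
  type <- match.arg(type)
  if (type == "reversible") {
    fp <- f_path_ramp(0.5, 0, up = 35L, down = 15L, hold = 20L,
                      peak_hold = 5L)
    return(simulate_hysteretic_stock(fp, allee_A = 0,
                                     process_sd = process_sd %||% 0.05,
                                     seed = seed))
  }
  truth <- .bifurcation_truth(r_growth = 0.9, K = 1e5, allee_A = 2e4,
                              floor = 5e3, f_grid_step = 1e-3)
  f_end <- if (type == "closed") 0.4 * truth$recovery_F
           else 1.5 * truth$recovery_F
  fp <- f_path_ramp(1.2 * truth$collapse_F, f_end, up = 25L,
                    peak_hold = 15L, down = 10L, hold = 30L)
  simulate_hysteretic_stock(fp, process_sd = process_sd %||% 0.03,
                            seed = seed)
}

#' End-to-end demonstration stocks for the three-flag pipeline
#'
#' Two fixed constructions used to exercise [run_three_flags()]:
#' `"all_effects"` embeds every regime-shift feature at once — the
#' closed-loop collapse/recovery trajectory of [loop_scenario()] (abrupt SSB
#' shifts and hysteresis), a temporal stock-recruitment regime change at the
#' collapse (dome-shaped SRR before, weak linear SRR after), and a coincident
#' sea-surface-temperature step so recruitment regimes split at an SST
#' threshold near 11.9 degC. `"null"` is a stationary logistic stock under
#' mildly varying F with a single-regime Ricker SRR and an SST series with no
#' effect, so no flag should be raised.
#'
#' @param type `"all_effects"` or `"null"`.
#' @param seed Integer seed.
#' @return A list with elements `stock` (a [stock_series()]) and `env` (an
#'   [env_series()]); truth in [sim_truth()] of the list.
#' @export
pipeline_scenario <- function(type = c("all_effects", "null"), seed = 1L) {
  type <- match.arg(type)
  if (type == "all_effects") {
    st <- loop_scenario("closed", seed = seed)
    n <- nrow(st)
    set.seed(seed + 7L)
    s <- st$ssb
    coll <- which(s < 0.3 * max(s))[1]
    era2 <- seq_len(n) >= coll
    sst <- ifelse(era2, rnorm(n, 13.6, 0.5), rnorm(n, 10.2, 0.5))
    r <- ifelse(era2, 0.6 * s, 65000 * exp(-((s - 55000) / 30000)^2))
    st$recruitment <- pmax(r * exp(rnorm(n, 0, 0.10)), 1)
    out <- list(stock = st, env = env_series(st$year, sst))
    attr(out, "truth") <- c(sim_truth(st), list(
      srr_break_year = st$year[coll],
      true_sst_threshold = (13.6 + 10.2) / 2,
      seed = seed))
    return(out)
  }
  set.seed(seed)
  n <- 60L
  f <- 0.25 + as.numeric(stats::arima.sim(list(ar = 0.6), n, sd = 0.02))
  f <- pmin(pmax(f, 0), 0.5)
  st <- simulate_hysteretic_stock(f, allee_A = 0, process_sd = 0.05,
                                  seed = seed + 1L)
  set.seed(seed + 2L)
  st$recruitment <- pmax(
    st$ssb * exp(1 - 1.2e-5 * st$ssb) * exp(rnorm(n, 0, 0.2)), 1)
  sst <- runif(n, 8, 16)
  out <- list(stock = st, env = env_series(st$year, sst))
  attr(out, "truth") <- list(seed = seed)
  out
}
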