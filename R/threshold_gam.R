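#' @section Threshold GAM:
#' The temperature flag asks whether the SSB-to-recruitment smooth switches
#' between two regimes at a sea-surface-temperature threshold. Candidate
#' thresholds are an even grid between the lower and upper SST quantiles
#' (defaults 0.2 and 0.8); for each, observations are partitioned by SST and a
#' model with a shared intercept and separate penalized-spline smooths of SSB
#' (basis dimension 4) per regime is fitted, each smoothing parameter chosen
#' by GCV. The threshold minimising GCV is returned with its full profile, and
#' the decision for a true threshold additionally requires a leave-one-out
#' preference for the threshold model and three criteria: differing effective
#' degrees of freedom between regimes, at least one significant regime slope,
#' and a deep valley in the GCV profile.
#' @name threshold_gam
NULL

# equally spaced B-spline basis of dimension k (degree min(3, k - 1)); x is
# clamped to the training range so left-out extremes remain predictable
.bspline_spec <- function(rng, k) {
  degree <- min(3L, k - 1L)
  n_inner <- k - degree - 1L
  inner <- if (n_inner > 0) {
    seq(rng[1], rng[2], length.out = n_inner + 2L)[-c(1L, n_inner + 2L)]
  } else numeric(0)
  knots <- c(rep(rng[1], degree + 1L), inner, rep(rng[2], degree + 1L))
  list(knots = knots, degree = degree, rng = rng, k = k)
}

.bspline_eval <- function(spec, x) {
  x <- pmin(pmax(x, spec$rng[1]), spec$rng[2])
  splines::splineDesign(spec$knots, x, ord = spec$degree + 1L)
}

.second_diff_penalty <- function(k) {
  D <- diff(diag(k), differences = 2L)
  crossprod(D)
}

#' Fit a penalized regression spline with GCV-selected smoothing
#'
#' A P-spline smooth of `y` on `x`: B-spline basis of dimension `k` on
#' equally spaced knots with a second-difference coefficient penalty, the
#' smoothing parameter chosen by minimising
#' \eqn{GCV = n\,RSS/(n - tr)^2} over `lambda_grid`, where `tr` is the trace
#' of the smoother matrix. The penalty's null space is the linear functions,
#' so as \eqn{\lambda \to \infty} the fit tends to the OLS line. The reported
#' `edf` excludes the intercept (so `edf = 1` is a linear fit); the full trace
#' used in the GCV denominator is kept as `edf_total`. Deterministic.
#'
#' @param x,y Predictor and response.
#' @param k Basis dimension (>= 3; cubic for `k >= 4`, quadratic at `k = 3`).
#' @param lambda_grid Positive smoothing-parameter grid.
#' @return A `gam_fit`: coefficients, `lambda`, `edf`, `edf_total`, `gcv`,
#'   `fitted`, the basis spec and the GCV path.
#' @export
fit_pspline_gam <- function(x, y, k = 3L,
                            lambda_grid = 10^seq(-4, 8, by = 0.25)) {
  n <- length(x)
  if (length(y) != n) abort("x and y must be equally long",
                            class = "fishshift_input_error")
  if (k < 3) abort("k must be >= 3", class = "fishshift_input_error")
  if (n < k + 2) abort("need n >= k + 2", class = "fishshift_input_error")
  if (diff(range(x)) == 0) abort("x has zero range",
                                 class = "fishshift_degenerate_error")
  spec <- .bspline_spec(range(x), k)
  B <- .bspline_eval(spec, x)
  P <- .second_diff_penalty(k)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  yy <- sum(y^2)
  path <- purrr::map_dfr(lambda_grid, function(lam) {
    K <- BtB + lam * P
    Kinv <- tryCatch(chol2inv(chol(K)), error = function(e) NULL)
    if (is.null(Kinv)) return(tibble(lambda = lam, gcv = Inf, tr = NA_real_))
    beta <- Kinv %*% Bty
    rss <- max(yy - 2 * sum(beta * Bty) + sum(beta * (BtB %*% beta)), 0)
    tr <- sum(Kinv * BtB)
    tibble(lambda = lam, gcv = n * rss / (n - tr)^2, tr = tr)
  })
  # ties (e.g. an exact fit at every lambda) resolve to the smoothest model
  gmin <- min(path$gcv)
  best <- max(which(path$gcv <= gmin + 1e-10 * (abs(gmin) + 1e-300) +
                      .Machine$double.eps))
  lam <- lambda_grid[best]
  K <- BtB + lam * P
  Kinv <- chol2inv(chol(K))
  beta <- as.numeric(Kinv %*% Bty)
  fitted <- as.numeric(B %*% beta)
  tr <- sum(Kinv * BtB)
  structure(list(
    k = k, coefficients = beta, lambda = lam,
    edf = tr - 1, edf_total = tr,
    gcv = n * sum((y - fitted)^2) / (n - tr)^2,
    fitted = fitted, spec = spec, gcv_path = path,
    x = x, y = y
  ), class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("<gam_fit> k = %d, lambda = %.3g, edf = %.2f, GCV = %.4g\n",
              x$k, x$lambda, x$edf, x$gcv))
  invisible(x)
}

#' @export
predict.gam_fit <- function(object, newdata, ...) {
  as.numeric(.bspline_eval(object$spec, newdata) %*% object$coefficients)
}

# design and penalties of the two-regime model for one candidate threshold.
# The regimes partition the rows, so giving each regime its own uncentred
# B-spline block (which spans that regime's level) keeps the design full rank
# while letting the regimes differ in mean as well as shape — indicator-`by`
# smooths behave the same way in the reference GAM machinery.
.tgam_design <- function(s, below, k) {
  spec <- .bspline_spec(range(s), k)
  B <- .bspline_eval(spec, s)
  P <- .second_diff_penalty(k)
  X <- cbind(B * as.numeric(below), B * as.numeric(!below))
  p <- 2L * k
  embed <- function(cols) {
    out <- matrix(0, p, p)
    out[cols, cols] <- P
    out
  }
  i1 <- seq_len(k)
  i2 <- k + seq_len(k)
  list(X = X, P1 = embed(i1), P2 = embed(i2),
       cols_below = i1, cols_above = i2, spec = spec)
}

.tgam_solve <- function(X, y, P1, P2, l1, l2) {
  G <- crossprod(X)
  K <- G + l1 * P1 + l2 * P2
  Kinv <- tryCatch(chol2inv(chol(K)), error = function(e) NULL)
  if (is.null(Kinv)) return(NULL)
  beta <- as.numeric(Kinv %*% crossprod(X, y))
  fitted <- as.numeric(X %*% beta)
  n <- length(y)
  M <- Kinv %*% G
  tr <- sum(diag(M))
  list(beta = beta, fitted = fitted, rss = sum((y - fitted)^2),
       tr = tr, edf_cols = diag(M), Kinv = Kinv,
       gcv = n * sum((y - fitted)^2) / (n - tr)^2)
}

# Wald p-value of the linear trend of one regime's predictions, with the
# trend's variance propagated through the smoother matrix
.regime_slope_p <- function(X, Kinv, fitted, rss, tr, s, sel) {
  n <- length(s)
  if (sum(sel) < 3 || sd(s[sel]) == 0) return(NA_real_)
  cvec <- numeric(n)
  sc <- s[sel] - mean(s[sel])
  cvec[sel] <- sc / sum(sc^2)
  slope <- sum(cvec * fitted)
  sigma2 <- rss / max(n - tr, 1)
  v <- X %*% (Kinv %*% crossprod(X, cvec))
  se <- sqrt(sigma2 * sum(v^2))
  if (!is.finite(se) || se == 0) return(NA_real_)
  2 * pnorm(-abs(slope / se))
}

.join_srr_env <- function(srr, env) {
  m <- merge(as.data.frame(srr), as.data.frame(env), by = "year")
  m <- m[complete.cases(m[, c("s", "r", "sst")]), ]
  as_tibble(m[order(m$year), ])
}

#' Fit a threshold GAM of recruitment on SSB split by SST
#'
#' Searches `grid_size` evenly spaced candidate SST thresholds between the
#' `lower_q` and `upper_q` SST quantiles. For each candidate the observations
#' are partitioned into SST-below and SST-above regimes and a model with a
#' separate penalized-spline smooth of SSB (basis dimension `k`, including the
#' regime's level) per regime is fitted, the two smoothing parameters selected
#' by overall GCV
#' over `lambda_grid`; candidates leaving a regime with fewer than
#' `min_per_regime` observations are skipped. The candidate with the minimal
#' GCV is returned together with the full GCV profile, per-regime effective
#' degrees of freedom and regime-trend p-values, and the lag-1 residual
#' autocorrelation as a diagnostic (it never gates any decision).
#'
#' @param srr An `srr_data` tibble (spawn-year pairs).
#' @param env An `env_series` tibble of annual SST.
#' @param k Basis dimension per regime smooth (default 4).
#' @param lower_q,upper_q Quantile bounds of the threshold search.
#' @param grid_size Number of candidate thresholds.
#' @param lambda_grid Smoothing-parameter grid (used for both regimes).
#' @param min_per_regime Minimum observations per regime.
#' @return A `tgam_fit`.
#' @export
fit_threshold_gam <- function(srr, env, k = 4L, lower_q = 0.2, upper_q = 0.8,
                              grid_size = 20L,
                              lambda_grid = 10^seq(-3, 7, length.out = 9),
                              min_per_regime = 5L) {
  if (lower_q >= upper_q) abort("lower_q must be below upper_q",
                                class = "fishshift_input_error")
  dat <- .join_srr_env(srr, env)
  n <- nrow(dat)
  if (n < 20) abort("need >= 20 overlapping stock-recruitment/SST years",
                    class = "fishshift_input_error")
  qs <- quantile(dat$sst, c(lower_q, upper_q), names = FALSE)
  cands <- seq(qs[1], qs[2], length.out = grid_size)
  lam2 <- expand.grid(l1 = lambda_grid, l2 = lambda_grid)
  profile <- purrr::map_dfr(cands, function(th) {
    below <- dat$sst <= th
    if (sum(below) < min_per_regime || sum(!below) < min_per_regime) {
      return(tibble(threshold = th, gcv = NA_real_,
                    l1 = NA_real_, l2 = NA_real_))
    }
    des <- .tgam_design(dat$s, below, k)
    gcvs <- vapply(seq_len(nrow(lam2)), function(j) {
      f <- .tgam_solve(des$X, dat$r, des$P1, des$P2, lam2$l1[j], lam2$l2[j])
      if (is.null(f)) Inf else f$gcv
    }, numeric(1))
    # ties (exact fits) resolve to the smoothest pair; the grid is ordered
    # with the largest lambdas last
    gmin <- min(gcvs)
    j <- max(which(gcvs <= gmin + 1e-10 * (abs(gmin) + 1e-300) +
                     .Machine$double.eps))
    tibble(threshold = th, gcv = gcvs[j], l1 = lam2$l1[j], l2 = lam2$l2[j])
  })
  if (all(is.na(profile$gcv))) {
    abort("every candidate threshold left a regime with too few observations",
          class = "fishshift_threshold_error")
  }
  best <- profile[which.min(profile$gcv), ]
  below <- dat$sst <= best$threshold
  des <- .tgam_design(dat$s, below, k)
  fit <- .tgam_solve(des$X, dat$r, des$P1, des$P2, best$l1, best$l2)
  # each regime block spans its own level; subtracting it reports the smooth
  # edf in the usual convention (edf = 1 is a linear regime)
  edf_below <- sum(fit$edf_cols[des$cols_below]) - 1
  edf_above <- sum(fit$edf_cols[des$cols_above]) - 1
  res <- dat$r - fit$fitted
  acf1 <- if (n > 2) stats::acf(res, plot = FALSE, lag.max = 1)$acf[2]
          else NA_real_
  structure(list(
    threshold = best$threshold,
    gcv = best$gcv,
    gcv_profile = profile,
    lambda_below = best$l1, lambda_above = best$l2,
    edf_below = edf_below, edf_above = edf_above,
    slope_p_below = .regime_slope_p(des$X, fit$Kinv, fit$fitted, fit$rss,
                                    fit$tr, dat$s, below),
    slope_p_above = .regime_slope_p(des$X, fit$Kinv, fit$fitted, fit$rss,
                                    fit$tr, dat$s, !below),
    fitted = fit$fitted, data = dat, below = below,
    k = k, resid_acf1 = acf1,
    params = list(lower_q = lower_q, upper_q = upper_q,
                  grid_size = grid_size, lambda_grid = lambda_grid,
                  min_per_regime = min_per_regime)
  ), class = "tgam_fit")
}

#' @export
print.tgam_fit <- function(x, ...) {
  cat(sprintf(
    "<tgam_fit> SST threshold %.2f degC (GCV %.4g)\n  edf below/above: %.2f / %.2f; trend p below/above: %.3g / %.3g\n",
    x$threshold, x$gcv, x$edf_below, x$edf_above,
    x$slope_p_below, x$slope_p_above))
  invisible(x)
}

# leave-one-out RMSE of the plain (single-regime) P-spline GAM, smoothing
# re-selected in every fold
.gam_loocv_rmse <- function(s, r, k = 3L,
                            lambda_grid = 10^seq(-4, 8, by = 0.5)) {
  n <- length(s)
  err <- vapply(seq_len(n), function(i) {
    fit <- fit_pspline_gam(s[-i], r[-i], k = k, lambda_grid = lambda_grid)
    predict(fit, s[i]) - r[i]
  }, numeric(1))
  sqrt(mean(err^2))
}

#' Leave-one-out comparison of the threshold GAM against the plain GAM
#'
#' For every held-out year, both models are refitted on the remaining years —
#' the plain GAM (basis dimension `k_gam`) with its smoothing re-selected, and
#' the threshold GAM with threshold and both smoothing parameters re-selected
#' — and the held-out recruitment predicted. The threshold model is preferred
#' when its LOOCV RMSE is lower.
#'
#' @param srr An `srr_data` tibble.
#' @param env An `env_series` tibble.
#' @param k_gam Basis dimension of the plain GAM (default 3).
#' @param k_tgam Basis dimension per regime of the threshold GAM (default 4).
#' @param lower_q,upper_q,grid_size,lambda_grid,min_per_regime As in
#'   [fit_threshold_gam()].
#' @param max_fail_frac Maximum tolerated fraction of failed folds.
#' @return A `tgam_loocv` list: `prefers_tgam`, `rmse_tgam`, `rmse_gam` and
#'   per-fold predictions.
#' @export
loocv_tgam_vs_gam <- function(srr, env, k_gam = 3L, k_tgam = 4L,
                              lower_q = 0.2, upper_q = 0.8, grid_size = 20L,
                              lambda_grid = 10^seq(-3, 7, length.out = 9),
                              min_per_regime = 5L, max_fail_frac = 0.1) {
  dat <- .join_srr_env(srr, env)
  n <- nrow(dat)
  if (n < 20) abort("need >= 20 overlapping stock-recruitment/SST years",
                    class = "fishshift_input_error")
  qs <- quantile(dat$sst, c(lower_q, upper_q), names = FALSE)
  cands <- seq(qs[1], qs[2], length.out = grid_size)
  designs <- purrr::map(cands, function(th) {
    .tgam_design(dat$s, dat$sst <= th, k_tgam)
  })
  below_mat <- vapply(cands, function(th) as.integer(dat$sst <= th),
                      integer(n))
  cpp <- tgam_loocv_cpp(purrr::map(designs, "X"), dat$r,
                        purrr::map(designs, "P1"), purrr::map(designs, "P2"),
                        below_mat, lambda_grid, as.integer(min_per_regime))
  failed <- sum(cpp$threshold_index == 0)
  if (failed > max_fail_frac * n) {
    abort(sprintf("threshold GAM LOOCV failed in %d of %d folds", failed, n),
          class = "fishshift_decision_error")
  }
  ok <- cpp$threshold_index > 0
  rmse_tgam <- sqrt(mean((cpp$pred[ok] - dat$r[ok])^2))
  rmse_gam <- .gam_loocv_rmse(dat$s, dat$r, k = k_gam)
  structure(list(
    prefers_tgam = rmse_tgam < rmse_gam,
    rmse_tgam = rmse_tgam, rmse_gam = rmse_gam,
    pred_tgam = as.numeric(cpp$pred),
    fold_threshold = cands[pmax(cpp$threshold_index, 1)],
    n_failed_folds = failed, n = n
  ), class = "tgam_loocv")
}

.edf_band <- function(edf) {
  if (!is.finite(edf)) return(NA_character_)
  if (edf <= 1 + 1e-6) "linear"
  else if (edf <= 2) "weakly non-linear"
  else "strongly non-linear"
}

#' Decide for or against a true temperature threshold
#'
#' Applies the three acceptance criteria to a fitted threshold GAM:
#' (1) the effective degrees of freedom of the two regime smooths must differ
#' by at least `edf_min_gap`; (2) at least one regime trend must be
#' significant at `alpha`; (3) the GCV profile must show a deep valley — its
#' minimum at least `valley_depth` below the profile median (proportionally).
#' The verdict is `accepted` only if the leave-one-out comparison preferred
#' the threshold model *and* all three criteria hold.
#'
#' @param fit A `tgam_fit`.
#' @param loocv A `tgam_loocv` object or a logical (LOOCV preference).
#' @param edf_min_gap Minimum |edf difference| between regimes.
#' @param alpha Significance level for the regime trends.
#' @param valley_depth Required proportional depth of the GCV valley.
#' @return A `tgam_decision`: the flags, the verdict, the threshold when
#'   accepted, and the edf interpretation bands.
#' @export
evaluate_threshold_criteria <- function(fit, loocv, edf_min_gap = 0.5,
                                        alpha = 0.05, valley_depth = 0.05) {
  prefers <- if (inherits(loocv, "tgam_loocv")) loocv$prefers_tgam
             else isTRUE(loocv)
  prof <- fit$gcv_profile$gcv
  prof <- prof[is.finite(prof)]
  criteria <- list(
    edf_differ = is.finite(fit$edf_below) && is.finite(fit$edf_above) &&
      abs(fit$edf_below - fit$edf_above) >= edf_min_gap,
    any_slope_significant = isTRUE(
      min(fit$slope_p_below, fit$slope_p_above, na.rm = TRUE) < alpha),
    gcv_valley = length(prof) > 1 &&
      min(prof) <= (1 - valley_depth) * median(prof)
  )
  accepted <- prefers && all(unlist(criteria))
  structure(list(
    loocv_prefers_tgam = prefers,
    criteria = criteria,
    verdict = if (accepted) "accepted" else "rejected",
    threshold = if (accepted) fit$threshold else NA_real_,
    edf_below = fit$edf_below, edf_above = fit$edf_above,
    edf_band_below = .edf_band(fit$edf_below),
    edf_band_above = .edf_band(fit$edf_above),
    resid_acf1 = fit$resid_acf1,
    params = list(edf_min_gap = edf_min_gap, alpha = alpha,
                  valley_depth = valley_depth)
  ), class = "tgam_decision")
}

#' @export
print.tgam_decision <- function(x, ...) {
  cat(sprintf("<tgam_decision> verdict: %s\n", x$verdict))
  cat(sprintf("  LOOCV prefers threshold model: %s\n", x$loocv_prefers_tgam))
  cat(sprintf("  edf differ: %s | slope significant: %s | GCV valley: %s\n",
              x$criteria$edf_differ, x$criteria$any_slope_significant,
              x$criteria$gcv_valley))
  if (!is.na(x$threshold)) {
    cat(sprintf("  accepted SST threshold: %.2f degC\n", x$threshold))
  }
  invisible(x)
}

#' Full temperature-threshold assessment of a stock-recruitment dataset
#'
#' Runs [fit_threshold_gam()], [loocv_tgam_vs_gam()] and
#' [evaluate_threshold_criteria()] in sequence.
#'
#' @param srr An `srr_data` tibble.
#' @param env An `env_series` tibble.
#' @param ... Passed to the component functions where named accordingly.
#' @return A `tgam_decision` with the `tgam_fit` attached as `$fit` and the
#'   LOOCV comparison as `$loocv`.
#' @export
assess_sst_threshold <- function(srr, env, ...) {
  args <- list(...)
  pick <- function(f) args[intersect(names(args), names(formals(f)))]
  fit <- do.call(fit_threshold_gam, c(list(srr, env), pick(fit_threshold_gam)))
  cv <- do.call(loocv_tgam_vs_gam, c(list(srr, env), pick(loocv_tgam_vs_gam)))
  dec <- do.call(evaluate_threshold_criteria,
                 c(list(fit, cv), pick(evaluate_threshold_criteria)))
  dec$fit <- fit
  dec$loocv <- cv
  dec
}
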