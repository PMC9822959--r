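#' @section Stock-recruitment model competition:
#' The third regime-shift flag asks whether the stock-recruitment relationship
#' (SRR) is stationary. Candidate models — Beverton-Holt
#' \eqn{R = \alpha S / (1 + \beta S)}, Ricker \eqn{R = S e^{\alpha - \beta S}},
#' linear, log-log linear, a one-breakpoint segmented GLM and a
#' breakpoint-regression model over spawn years — are fitted to the aligned
#' spawn-year pairs and compared by leave-one-out cross-validation on the raw
#' recruitment scale. A discontinuous winner flags non-stationarity.
#' @name srr_models
NULL

.new_srr_fit <- function(model_kind, data, fitted_raw, sse, scale,
                         alpha = NA_real_, beta = NA_real_, psi = NA_real_,
                         segment_params = NULL, flags = character(0),
                         extra = list()) {
  structure(c(list(
    model_kind = model_kind, alpha = alpha, beta = beta, psi = psi,
    segment_params = segment_params, fitted = pmax(fitted_raw, 0),
    sse = sse, sse_scale = scale, flags = flags, data = data
  ), extra), class = "srr_fit")
}

#' @export
print.srr_fit <- function(x, ...) {
  cat(sprintf("<srr_fit> %s (n = %d)\n", x$model_kind, nrow(x$data)))
  if (!is.na(x$alpha)) cat(sprintf("  alpha = %.6g\n", x$alpha))
  if (!is.na(x$beta)) cat(sprintf("  beta  = %.6g\n", x$beta))
  if (!is.na(x$psi)) cat(sprintf("  psi   = %.6g (SSB breakpoint)\n", x$psi))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit a Beverton-Holt stock-recruitment curve
#'
#' Nonlinear least squares of \eqn{R = \alpha S / (1 + \beta S)} under
#' multiplicative lognormal error, i.e. minimising
#' \eqn{\sum (\log r - \log(\alpha s / (1 + \beta s)))^2}. Starting values
#' come from OLS on the linearisation \eqn{1/r = (1/\alpha)(1/s) +
#' \beta/\alpha}; on non-convergence a small restart grid around the start is
#' tried and the best attempt returned with a flag. A negative \eqn{\beta}
#' estimate is permitted but flagged.
#'
#' @param data An `srr_data` tibble (columns `s`, `r`).
#' @return An `srr_fit`; `sse` is on the log scale, `fitted` on the raw scale.
#' @export
fit_beverton_holt <- function(data) {
  if (nrow(data) < 5) abort("need at least 5 stock-recruitment pairs",
                            class = "fishshift_input_error")
  s <- data$s; r <- data$r
  lin <- lm(I(1 / r) ~ I(1 / s))
  a0 <- 1 / coef(lin)[[2]]
  b0 <- coef(lin)[[1]] * a0
  if (!is.finite(a0) || a0 <= 0) a0 <- stats::median(r / s)
  if (!is.finite(b0)) b0 <- 1 / stats::median(s)
  # keep 1 + beta*s positive over the observed range so the log stays finite;
  # beta may still go (slightly) negative and is then flagged
  b_lo <- -0.99 / max(s)
  b0 <- max(b0, b_lo * 0.5)
  # the linearised start can already be the exact solution (noiseless data);
  # nonlinear optimisers stall on zero residuals, so return it directly
  sse0 <- sum((log(r) - log(pmax(a0 * s / (1 + b0 * s), 1e-300)))^2)
  if (is.finite(sse0) && sse0 < 1e-18) {
    return(.new_srr_fit("beverton_holt", data, a0 * s / (1 + b0 * s), sse0,
                        "log", alpha = a0, beta = b0))
  }
  starts <- list(c(a0, b0))
  for (m in c(0.25, 4)) starts <- c(starts, list(c(a0 * m, b0), c(a0, b0 * m)))
  best <- NULL
  flags <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(log(r) ~ log(alpha * s / (1 + beta * s)),
                        start = list(alpha = st[1], beta = max(st[2], b_lo * 0.5)),
                        lower = c(alpha = 1e-12, beta = b_lo),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(resid(fit)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(fit = fit, sse = sse)
      }
    }
  }
  if (is.null(best)) {
    abort("Beverton-Holt fit failed to converge from every start",
          class = "fishshift_fit_error")
  }
  a <- coef(best$fit)[["alpha"]]; b <- coef(best$fit)[["beta"]]
  if (b < 0) flags <- c(flags, "beta < 0 (no asymptote within data)")
  .new_srr_fit("beverton_holt", data, a * s / (1 + b * s), best$sse, "log",
               alpha = a, beta = b, flags = flags)
}

#' Fit a Ricker stock-recruitment curve
#'
#' The exact least-squares solution under multiplicative lognormal error:
#' OLS on the linearised form \eqn{\log(r/s) = \alpha - \beta s}.
#'
#' @param data An `srr_data` tibble.
#' @return An `srr_fit`; `sse` on the log scale, `fitted` raw.
#' @export
fit_ricker <- function(data) {
  if (nrow(data) < 5) abort("need at least 5 stock-recruitment pairs",
                            class = "fishshift_input_error")
  s <- data$s; r <- data$r
  if (length(unique(s)) < 3) {
    abort("need at least 3 distinct SSB values",
          class = "fishshift_degenerate_error")
  }
  fit <- lm(log(r / s) ~ s)
  a <- coef(fit)[[1]]
  b <- -coef(fit)[[2]]
  flags <- if (b < 0) "beta < 0 (non-dome-shaped)" else character(0)
  .new_srr_fit("ricker", data, s * exp(a - b * s), sum(resid(fit)^2), "log",
               alpha = a, beta = b, flags = flags)
}

#' Fit a linear or log-log linear stock-recruitment model
#'
#' OLS of recruitment on SSB, optionally after log transformation of both
#' variables; fitted values are back-transformed to the raw scale.
#'
#' @param data An `srr_data` tibble.
#' @param log_scale If `TRUE`, fit `log r ~ log s`.
#' @return An `srr_fit` of kind `linear` or `loglog_linear`.
#' @export
fit_srr_linear <- function(data, log_scale = FALSE) {
  if (nrow(data) < 3) abort("need at least 3 stock-recruitment pairs",
                            class = "fishshift_input_error")
  s <- data$s; r <- data$r
  if (sd(s) == 0) abort("SSB has zero variance",
                        class = "fishshift_degenerate_error")
  if (log_scale) {
    fit <- lm(log(r) ~ log(s))
    fitted_raw <- exp(fitted(fit))
    kind <- "loglog_linear"; scale <- "log"
  } else {
    fit <- lm(r ~ s)
    fitted_raw <- fitted(fit)
    kind <- "linear"; scale <- "raw"
  }
  .new_srr_fit(kind, data, fitted_raw, sum(resid(fit)^2), scale,
               alpha = coef(fit)[[1]], beta = coef(fit)[[2]])
}

#' Choose a GLM error family from residual dispersion
#'
#' Fits a log-link count GLM of recruitment on SSB and computes the Pearson
#' dispersion \eqn{\phi}. Near-equidispersion (`0.8 <= phi <= 1.2`) keeps the
#' Poisson family; moderate overdispersion (`1.2 < phi <= 5`) selects
#' quasi-Poisson; strong overdispersion (`phi > 5`) selects the negative
#' binomial. Recruitment rescaled away from count magnitudes (flagged by the
#' caller) selects the Gaussian family directly.
#'
#' @param data An `srr_data` tibble (at least 10 pairs).
#' @param rescaled Set `TRUE` when recruitment has been rescaled to
#'   non-count magnitudes.
#' @return A `family_choice` list: `family`, `dispersion`, `rationale`.
#' @export
choose_glm_family <- function(data, rescaled = FALSE) {
  if (nrow(data) < 10) abort("need at least 10 stock-recruitment pairs",
                             class = "fishshift_input_error")
  fit <- suppressWarnings(glm(r ~ s, data = data,
                              family = stats::quasipoisson()))
  phi <- sum(resid(fit, type = "pearson")^2) / fit$df.residual
  if (rescaled) {
    fam <- "gaussian"
    why <- "recruitment rescaled to non-count magnitudes"
  } else if (phi >= 0.8 && phi <= 1.2) {
    fam <- "poisson"
    why <- sprintf("Pearson dispersion %.2f within [0.8, 1.2]", phi)
  } else if (phi > 1.2 && phi <= 5) {
    fam <- "quasi_poisson"
    why <- sprintf("moderate overdispersion (%.2f)", phi)
  } else if (phi > 5) {
    fam <- "negative_binomial"
    why <- sprintf("strong overdispersion (%.2f)", phi)
  } else {
    fam <- "quasi_poisson"
    why <- sprintf("underdispersion (%.2f); quasi-likelihood retained", phi)
  }
  structure(list(family = fam, dispersion = phi, rationale = why),
            class = "family_choice")
}

.glm_fitter <- function(family) {
  switch(family,
    gaussian = function(fml, df) glm(fml, data = df, family = stats::gaussian()),
    poisson = function(fml, df) suppressWarnings(
      glm(fml, data = df, family = stats::poisson())),
    quasi_poisson = function(fml, df) suppressWarnings(
      glm(fml, data = df, family = stats::quasipoisson())),
    negative_binomial = function(fml, df) suppressWarnings(
      MASS::glm.nb(fml, data = df)),
    abort(paste0("unknown family: ", family), class = "fishshift_input_error")
  )
}

#' Fit a one-breakpoint segmented (G)LM stock-recruitment model
#'
#' Muggeo's iterative linearisation for a single breakpoint \eqn{\psi} on the
#' SSB axis: the linear predictor is augmented with
#' \eqn{U = (s - \psi)_+} and \eqn{V = -1[s > \psi]}, the model refitted, and
#' \eqn{\psi} updated by the ratio of the `V` to the `U` coefficient until the
#' step falls below `tol`. The starting value is the mean of SSB. The final
#' refit drops `V`; the slope difference between regimes is the `U`
#' coefficient, whose Wald p-value decides whether the break is supported.
#'
#' @param data An `srr_data` tibble.
#' @param family A `family_choice`, a family name, or `NULL` for gaussian.
#' @param psi0 Starting breakpoint; defaults to `mean(s)`.
#' @param max_iter,tol Iteration control; `tol` is in SSB units (default
#'   `1e-6 * range(s)`).
#' @return An `srr_fit` of kind `segmented_glm` with `psi`, per-regime slopes
#'   in `segment_params`, and a `break_p_value`.
#' @export
fit_segmented_glm <- function(data, family = NULL, psi0 = NULL,
                              max_iter = 50L, tol = NULL) {
  if (nrow(data) < 10) abort("need at least 10 stock-recruitment pairs",
                             class = "fishshift_input_error")
  fam <- if (inherits(family, "family_choice")) family$family
         else if (is.null(family)) "gaussian" else family
  fitter <- .glm_fitter(fam)
  s <- data$s; r <- data$r
  rng <- range(s)
  if (is.null(tol)) tol <- 1e-6 * diff(rng)
  psi <- psi0 %||% mean(s)
  if (psi <= rng[1] || psi >= rng[2]) {
    abort("psi0 must lie strictly inside the observed SSB range",
          class = "fishshift_input_error")
  }
  flags <- character(0)
  clamp <- quantile(s, c(0.05, 0.95), names = FALSE)

  deviance_at <- function(psi_try) {
    df <- data.frame(r = r, s = s, U = pmax(s - psi_try, 0))
    fit <- tryCatch(fitter(r ~ s + U, df), error = function(e) NULL)
    if (is.null(fit)) Inf else stats::deviance(fit)
  }
  iterate <- function(psi_start) {
    psi_cur <- psi_start
    local_flags <- character(0)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      df <- data.frame(r = r, s = s,
                       U = pmax(s - psi_cur, 0),
                       V = -as.numeric(s > psi_cur))
      fit <- tryCatch(fitter(r ~ s + U + V, df), error = function(e) NULL)
      if (is.null(fit)) {
        abort("segmented fit failed during iteration",
              class = "fishshift_fit_error")
      }
      cf <- coef(fit)
      if (!is.finite(cf[["U"]]) || abs(cf[["U"]]) < 1e-12) {
        local_flags <- c(local_flags,
                         "no slope change detectable; psi update degenerate")
        break
      }
      psi_new <- psi_cur + cf[["V"]] / cf[["U"]]
      if (psi_new <= rng[1] || psi_new >= rng[2]) {
        psi_new <- min(max(psi_new, clamp[1]), clamp[2])
        local_flags <- unique(c(local_flags,
                                "psi clamped to interior quantile"))
      }
      if (abs(psi_new - psi_cur) < tol) {
        psi_cur <- psi_new
        conv <- TRUE
        break
      }
      psi_cur <- psi_new
    }
    list(psi = psi_cur, converged = conv, flags = local_flags,
         deviance = deviance_at(psi_cur))
  }

  run <- iterate(psi)
  # the iteration converges to the nearest fixed point; a coarse scan of
  # interior quantiles guards against a better distant basin
  cand <- unique(quantile(s, seq(0.1, 0.9, length.out = 17), names = FALSE))
  cand <- cand[cand > rng[1] & cand < rng[2]]
  dev_cand <- vapply(cand, deviance_at, numeric(1))
  if (any(dev_cand < run$deviance * (1 - 1e-8))) {
    run2 <- iterate(cand[which.min(dev_cand)])
    if (run2$deviance < run$deviance) run <- run2
  }
  # final polish: the RSS profile in psi is only piecewise smooth, so the
  # fixed point is finished off by a bounded one-dimensional search
  w <- 0.02 * diff(rng)
  opt <- tryCatch(
    stats::optimize(deviance_at, lower = max(rng[1] + tol, run$psi - w),
                    upper = min(rng[2] - tol, run$psi + w), tol = tol / 4),
    error = function(e) NULL)
  if (!is.null(opt) && opt$objective < run$deviance) {
    run$psi <- opt$minimum
    run$deviance <- opt$objective
  }
  psi <- run$psi
  converged <- run$converged
  flags <- unique(c(flags, run$flags))
  if (!converged) flags <- unique(c(flags, "psi iteration not converged"))
  df <- data.frame(r = r, s = s, U = pmax(s - psi, 0))
  final <- fitter(r ~ s + U, df)
  sm <- summary(final)$coefficients
  p_break <- if ("U" %in% rownames(sm)) sm["U", ncol(sm)] else NA_real_
  if (!is.na(p_break) && p_break >= 0.05) {
    flags <- unique(c(flags, "no supported break"))
  }
  slopes <- c(below = coef(final)[["s"]],
              above = coef(final)[["s"]] + coef(final)[["U"]])
  seg <- tibble(regime = c("below", "above"), slope = unname(slopes))
  fitted_raw <- as.numeric(predict(final, type = "response"))
  .new_srr_fit("segmented_glm", data, fitted_raw,
               sum((r - fitted_raw)^2), "raw",
               psi = psi, segment_params = seg, flags = flags,
               extra = list(break_p_value = p_break, family = fam,
                            model = final, converged = converged))
}

#' Breakpoint-regression stock-recruitment model over spawn years
#'
#' Orders the pairs by spawn year and applies [baiperron_breakpoints()] with
#' `y = r` and `x = s`, so breaks mark years at which the linear SRR changed;
#' each period gets its own linear SRR.
#'
#' @param data An `srr_data` tibble (at least 15 pairs).
#' @param max_breaks Maximum number of breaks.
#' @return An `srr_fit` of kind `breakpoint_regression` with `break_years`
#'   and the underlying `breakpoint_model` as `bp`.
#' @export
fit_srr_breakpoints <- function(data, max_breaks = 3L) {
  if (nrow(data) < 15) abort("need at least 15 stock-recruitment pairs",
                             class = "fishshift_input_error")
  data <- data[order(data$year), ]
  bp <- baiperron_breakpoints(data$s, data$r, max_breaks = max_breaks)
  fitted_raw <- numeric(nrow(data))
  bounds <- c(0L, bp$break_indices, nrow(data))
  for (i in seq_len(bp$n_breaks + 1)) {
    idx <- seq(bounds[i] + 1L, bounds[i + 1])
    cf <- bp$segment_coefficients[i, ]
    fitted_raw[idx] <- if (cf$intercept_only) cf$intercept else
      cf$intercept + cf$slope * data$s[idx]
  }
  seg <- bp$segment_coefficients
  seg$start_year <- data$year[seg$start_idx]
  seg$end_year <- data$year[seg$end_idx]
  .new_srr_fit("breakpoint_regression", data, fitted_raw,
               sum((data$r - fitted_raw)^2), "raw",
               segment_params = seg,
               extra = list(break_years = data$year[bp$break_indices + 1L],
                            bp = bp))
}

# unified fit/predict used by the LOOCV competition --------------------------

.fit_srr_kind <- function(data, kind, family = NULL) {
  switch(kind,
    linear = fit_srr_linear(data, log_scale = FALSE),
    loglog_linear = fit_srr_linear(data, log_scale = TRUE),
    ricker = fit_ricker(data),
    beverton_holt = fit_beverton_holt(data),
    segmented_glm = fit_segmented_glm(data, family = family),
    breakpoint_regression = fit_srr_breakpoints(data),
    abort(paste0("unknown SRR model kind: ", kind),
          class = "fishshift_input_error")
  )
}

#' Predict recruitment from a fitted SRR model (raw scale)
#'
#' @param fit An `srr_fit`.
#' @param s New SSB values (tonnes).
#' @param year Spawn years of the new values; required for
#'   `breakpoint_regression`, whose prediction depends on the period.
#' @return Predicted recruitment, floored at zero.
#' @export
predict_srr <- function(fit, s, year = NULL) {
  out <- switch(fit$model_kind,
    linear = fit$alpha + fit$beta * s,
    loglog_linear = exp(fit$alpha) * s^fit$beta,
    ricker = s * exp(fit$alpha - fit$beta * s),
    beverton_holt = fit$alpha * s / (1 + fit$beta * s),
    segmented_glm = as.numeric(predict(fit$model,
      newdata = data.frame(s = s, U = pmax(s - fit$psi, 0)),
      type = "response")),
    breakpoint_regression = {
      if (is.null(year)) abort("breakpoint_regression prediction needs year",
                               class = "fishshift_input_error")
      seg <- fit$segment_params
      k <- findInterval(year, c(-Inf, fit$break_years))
      k <- pmin(pmax(k, 1L), nrow(seg))
      ifelse(seg$intercept_only[k], seg$intercept[k],
             seg$intercept[k] + seg$slope[k] * s)
    },
    abort(paste0("unknown SRR model kind: ", fit$model_kind),
          class = "fishshift_input_error")
  )
  pmax(out, 0)
}

#' Leave-one-out competition of stock-recruitment models
#'
#' For every observation, each candidate is refitted on the remaining pairs
#' and its prediction error at the held-out pair recorded; all errors are on
#' the raw recruitment scale so models fitted on different scales stay
#' commensurate. Following the package's selection rule, the winner is the
#' candidate with the lowest *training* RMSE (mean in-sample RMSE across
#' folds); the test RMSE is always reported alongside. A candidate that fails
#' to fit on any fold is excluded and flagged.
#'
#' @param data An `srr_data` tibble with at least 10 pairs.
#' @param candidates Character vector of model kinds (see [predict_srr()]).
#' @param family Optional family (for the segmented GLM candidate).
#' @return A `model_comparison`: `table` (per-model train/test RMSE and
#'   status), `winner`, and the full-data `fits`.
#' @export
loocv_compare <- function(data,
                          candidates = c("linear", "loglog_linear", "ricker",
                                         "beverton_holt", "segmented_glm"),
                          family = NULL) {
  n <- nrow(data)
  if (n < 10) abort("need at least 10 stock-recruitment pairs",
                    class = "fishshift_input_error")
  res <- purrr::map(candidates, function(kind) {
    test_err <- rep(NA_real_, n)
    train_rmse <- rep(NA_real_, n)
    failed <- 0L
    for (i in seq_len(n)) {
      sub <- data[-i, ]
      fit <- tryCatch(suppressWarnings(.fit_srr_kind(sub, kind, family)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        failed <- failed + 1L
        next
      }
      train_rmse[i] <- sqrt(mean((fit$fitted - sub$r)^2))
      test_err[i] <- predict_srr(fit, data$s[i], data$year[i]) - data$r[i]
    }
    tibble(model_kind = kind,
           rmse_train = mean(train_rmse, na.rm = TRUE),
           rmse_test = sqrt(mean(test_err^2, na.rm = TRUE)),
           n_failed_folds = failed)
  })
  tab <- bind_rows(res)
  ok <- tab$n_failed_folds == 0
  if (!any(ok)) abort("every candidate failed at least one fold",
                      class = "fishshift_comparison_error")
  excluded <- tab$model_kind[!ok]
  winner <- tab$model_kind[ok][which.min(tab$rmse_train[ok])]
  fits <- purrr::map(
    setNames(candidates, candidates),
    function(kind) tryCatch(suppressWarnings(.fit_srr_kind(data, kind, family)),
                            error = function(e) NULL))
  structure(list(table = tab, winner = winner, excluded = excluded,
                 fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> winner:", x$winner, "\n")
  print(x$table)
  if (length(x$excluded)) {
    cat("  excluded (failed folds):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
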