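#' Average replicate residual-mass observations per time point
#'
#' The kinetic model is fitted to the per-time-point average of the
#' replicates, because the replicate vials sacrificed at one sampling time
#' are not independent trajectories: treating them as separate data points
#' would overstate the information content of the series.
#'
#' @param dataset A `residual_mass_dataset` (from
#'   [simulate_mass_timeseries()] or [read_mass_csv()]), or any data.frame
#'   with columns `time_d` and `residual_percent`.
#' @return An `averaged_series`: a data.frame with one row per time point
#'   and columns `time_d`, `mean_percent`, `sd_percent` (sample sd, `NA`
#'   for a single replicate) and `n_replicates`.
#' @export
average_replicates <- function(dataset) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0) {
    stop_field("dataset", "must be a non-empty data.frame")
  }
  if (!all(c("time_d", "residual_percent") %in% names(dataset))) {
    stop_field("dataset", "needs columns time_d and residual_percent")
  }
  sp <- split(dataset$residual_percent, dataset$time_d)
  out <- data.frame(
    time_d = as.numeric(names(sp)),
    mean_percent = vapply(sp, mean, numeric(1)),
    sd_percent = vapply(sp, function(x) {
      if (length(x) > 1) stats::sd(x) else NA_real_
    }, numeric(1)),
    n_replicates = vapply(sp, length, integer(1)),
    row.names = NULL)
  out <- out[order(out$time_d), , drop = FALSE]
  structure(out, class = c("averaged_series", "data.frame"))
}

#' Fit the shoulder-log-linear model to an averaged series
#'
#' Least-squares fit of the shoulder-log-linear decay model to per-time
#' mean residual percentages, with the initial mass fixed (default 100%,
#' the normalized added mass). Either both `k` and the lag `L` are fitted
#' (`fix_lag_to_zero = FALSE`) or the lag is pinned at zero, giving the
#' ordinary pseudo-first-order model.
#'
#' Optimization uses Levenberg-Marquardt with box bounds
#' (`k` in \[0, 10\] d^-1, `lag` in \[0, max(times)\]); starting values come
#' from an OLS slope of `log(mean)` over the declining phase and from the
#' latest time at which the mean is still >= 95% of `m0`; up to 10 jittered
#' restarts are attempted on failure. Standard errors derive from the
#' Gauss-Newton covariance `s^2 (J'J)^-1` with `s^2 = RSS/(n - p)`, and
#' p-values are two-sided Wald t-tests on `n - p` degrees of freedom.
#'
#' Reported fit statistics: `r_squared = 1 - RSS/TSS`;
#' `neg2loglik = n (log(2 pi RSS / n) + 1)` (Gaussian likelihood at the MLE
#' variance `RSS/n`, additive constants included, so only differences
#' between models on the same series are meaningful);
#' `aic = neg2loglik + 2 p`; `bic = neg2loglik + p log(n)`; `chi_squared`
#' is the replicate-variance-weighted statistic
#' `sum((mean_i - model_i)^2 / (sd_i^2 / n_i))` when every time point has a
#' positive replicate sd, otherwise the plain RSS with
#' `chi_squared_is_rss = TRUE`.
#'
#' @param series An `averaged_series` from [average_replicates()].
#' @param fix_lag_to_zero If TRUE, fit the pure first-order model (lag = 0).
#' @param m0_fixed Fixed initial value on the percent scale (default 100).
#' @return A `kinetic_fit` list; see Details. `converged = FALSE` with
#'   diagnostics if the optimizer failed after all restarts.
#' @examples
#' d <- simulate_mass_timeseries(
#'   kinetic_params(100, k = 0.081, lag = 24),
#'   sampling_design(seq(0, 70, by = 7)),
#'   noise_model(sigma_abs = 0, seed = 1))
#' fit_shoulder_log_linear(average_replicates(d))
#' @export
fit_shoulder_log_linear <- function(series, fix_lag_to_zero = FALSE,
                                    m0_fixed = 100) {
  if (!inherits(series, "averaged_series")) {
    stop_field("series", "must be an averaged_series (see average_replicates)")
  }
  check_flag(fix_lag_to_zero, "fix_lag_to_zero")
  check_scalar_num(m0_fixed, "m0_fixed", lower = 0, allow_zero = FALSE)
  n <- nrow(series)
  p <- if (fix_lag_to_zero) 1L else 2L
  if (n < p + 1L) {
    stop_field("series", sprintf(
      "needs at least %d time points to fit %d parameter(s)", p + 1L, p))
  }
  t <- series$time_d
  y <- series$mean_percent
  t_max <- max(t)

  # starting values: log-linear slope over the declining phase, lag from
  # the last time the series is still within 5% of the initial mass
  lag0 <- if (fix_lag_to_zero) 0 else {
    below <- t[y >= 0.95 * m0_fixed]
    if (length(below) > 0 && max(below) < t_max) max(below) else 0
  }
  decl <- which(t >= lag0 & y > 0)
  k0 <- 0.01
  if (length(decl) >= 2) {
    sl <- stats::coef(stats::lm(log(y[decl]) ~ t[decl]))[[2]]
    if (is.finite(sl) && sl < 0) k0 <- min(max(-sl, 1e-6), 10)
  }

  fitfun <- if (fix_lag_to_zero) {
    function(par) shoulder_mass(t, m0_fixed, par[[1]], 0)
  } else {
    function(par) shoulder_mass(t, m0_fixed, par[[1]], par[[2]])
  }
  start <- if (fix_lag_to_zero) c(k = k0) else c(k = k0, lag = lag0)
  lower <- if (fix_lag_to_zero) 0 else c(0, 0)
  upper <- if (fix_lag_to_zero) 10 else c(10, t_max)

  run_nls <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(par) y - fitfun(par),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  # nls.lm info codes 1-4 signal convergence, 6-8 a solution at numerical
  # precision limits (still usable); 0 and 5 warrant a jittered restart
  ok <- function(res) !inherits(res, "error") && res$info %in% c(1:4, 6:8)
  res <- run_nls(start)
  restarts <- 0L
  while (!ok(res) && restarts < 10L) {
    restarts <- restarts + 1L
    # deterministic jitter sequence keyed on the restart index
    jit <- withr::with_seed(restarts, {
      st <- start
      st[["k"]] <- min(max(start[["k"]] * exp(stats::rnorm(1, 0, 1)),
                           1e-6), 10)
      if (!fix_lag_to_zero) st[["lag"]] <- stats::runif(1, 0, t_max)
      st
    })
    res <- run_nls(jit)
  }
  if (!fix_lag_to_zero && ok(res)) {
    # the shoulder model nests pure exponential decay, so a free-lag fit
    # must never be worse than the best lag = 0 fit; restarting from that
    # solution escapes shoulder-side local minima (LM descends on the RSS)
    zero_sol <- tryCatch(
      minpack.lm::nls.lm(
        par = c(k = k0),
        fn = function(par) y - shoulder_mass(t, m0_fixed, par[[1]], 0),
        lower = 0, upper = 10,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(zero_sol) && ok(zero_sol)) {
      res2 <- run_nls(c(k = zero_sol$par[[1]], lag = 0))
      if (ok(res2) && res2$deviance < res$deviance) res <- res2
    }
  }
  if (!ok(res)) {
    return(structure(list(
      variant = if (fix_lag_to_zero) "lag-fixed-zero" else "free-lag",
      converged = FALSE, n_points = n, m0 = m0_fixed,
      diagnostics = list(
        message = if (inherits(res, "error")) conditionMessage(res)
                  else res$message,
        restarts = restarts, start = start)),
      class = "kinetic_fit"))
  }

  est <- res$par
  fitted <- fitfun(est)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df <- n - p
  s2 <- rss / df
  covm <- tryCatch(s2 * solve(res$hessian), error = function(e) NULL)
  # fall back to a finite-difference Jacobian when the returned Hessian is
  # singular (e.g. a parameter pinned at its bound)
  if (is.null(covm) || any(!is.finite(diag(covm))) || any(diag(covm) < 0)) {
    jac <- numeric_jacobian(fitfun, est)
    covm <- tryCatch(s2 * solve(crossprod(jac)), error = function(e) NULL)
  }
  se <- if (!is.null(covm)) sqrt(pmax(diag(covm), 0)) else rep(NA_real_, p)
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = df)

  neg2ll <- n * (log(2 * pi * rss / n) + 1)
  all_sd_ok <- all(is.finite(series$sd_percent) & series$sd_percent > 0)
  chi2 <- if (all_sd_ok) {
    sum(resid^2 / (series$sd_percent^2 / series$n_replicates))
  } else {
    rss
  }

  out <- list(
    variant = if (fix_lag_to_zero) "lag-fixed-zero" else "free-lag",
    converged = TRUE,
    k_hat = est[[1]],
    se_k = se[[1]],
    p_k = pval[[1]],
    lag_hat = if (fix_lag_to_zero) 0 else est[[2]],
    se_lag = if (fix_lag_to_zero) NA_real_ else se[[2]],
    p_lag = if (fix_lag_to_zero) NA_real_ else pval[[2]],
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    rss = rss,
    aic = neg2ll + 2 * p,
    bic = neg2ll + p * log(n),
    chi_squared = chi2,
    chi_squared_is_rss = !all_sd_ok,
    neg2loglik = neg2ll,
    n_points = n,
    n_params = p,
    m0 = m0_fixed,
    restarts = restarts,
    times = t,
    fitted = fitted)
  structure(out, class = "kinetic_fit")
}

numeric_jacobian <- function(f, par, eps = 1e-6) {
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    ph <- par
    h <- eps * max(abs(par[[j]]), 1)
    ph[[j]] <- par[[j]] + h
    J[, j] <- (f(ph) - f0) / h
  }
  J
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s, %d points\n", x$variant, x$n_points))
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED:", x$diagnostics$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  k   = %.4g +/- %.2g d^-1 (p = %.3g)\n",
              x$k_hat, x$se_k, x$p_k))
  if (x$variant == "free-lag") {
    cat(sprintf("  lag = %.4g +/- %.2g d (p = %.3g)\n",
                x$lag_hat, x$se_lag, x$p_lag))
  }
  cat(sprintf("  R^2 = %.4f, AIC = %.2f, BIC = %.2f\n",
              x$r_squared, x$aic, x$bic))
  invisible(x)
}

#' Choose between the free-lag and lag-zero kinetic fits
#'
#' Applies the lag-phase significance rule: the lag term is kept only when
#' its two-sided Wald p-value is at or below `alpha`; otherwise the
#' pure first-order fit (lag = 0) is reported. A p-value exactly at `alpha`
#' counts as significant. A missing lag p-value (e.g. a degenerate fit with
#' the lag at its bound and no usable curvature) is treated as not
#' significant.
#'
#' @param fit_free The free-lag `kinetic_fit`.
#' @param fit_zero The lag-fixed-zero `kinetic_fit` on the same series.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return The selected `kinetic_fit`, with a `selection` element recording
#'   the rule outcome and both models' comparison statistics
#'   (AIC, BIC, chi-squared, -2 log L).
#' @export
select_model <- function(fit_free, fit_zero, alpha = 0.05) {
  stopifnot(inherits(fit_free, "kinetic_fit"),
            inherits(fit_zero, "kinetic_fit"))
  if (fit_free$variant != "free-lag" || fit_zero$variant != "lag-fixed-zero") {
    stop_field("fit_free/fit_zero", "expected one free-lag and one lag-fixed-zero fit")
  }
  check_scalar_num(alpha, "alpha", lower = 0, allow_zero = FALSE)
  if (alpha >= 1) stop_field("alpha", "must be < 1")
  if (fit_free$n_points != fit_zero$n_points ||
      (isTRUE(fit_free$converged) && isTRUE(fit_zero$converged) &&
       !isTRUE(all.equal(fit_free$times, fit_zero$times)))) {
    stop_field("fit_zero", "fits were not computed on the same series")
  }
  lag_significant <- isTRUE(fit_free$converged) &&
    is.finite(fit_free$p_lag) && fit_free$p_lag <= alpha
  chosen <- if (lag_significant) fit_free else fit_zero
  stats_of <- function(f) {
    if (!isTRUE(f$converged)) return(list(converged = FALSE))
    list(aic = f$aic, bic = f$bic, chi_squared = f$chi_squared,
         neg2loglik = f$neg2loglik, rss = f$rss)
  }
  chosen$selection <- list(
    rule = "lag kept when p_lag <= alpha",
    alpha = alpha,
    lag_significant = lag_significant,
    p_lag = fit_free$p_lag,
    free_lag = stats_of(fit_free),
    lag_zero = stats_of(fit_zero))
  chosen
}
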