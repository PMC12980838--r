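#' Universal gas constant (J K^-1 mol^-1)
#' @export
GAS_CONSTANT <- 8.314

#' Temperature-resolved rate constants for one soil/polymer combination
#'
#' @param temperature_c Incubation temperatures (degrees C), distinct.
#' @param k_per_day Pseudo-first-order rate constants (d^-1), all > 0 so
#'   that `log(k)` is finite.
#' @param soil,variant Metadata labels.
#' @param se_k Optional per-point standard errors of `k`, carried as
#'   metadata (the Arrhenius regression itself is unweighted).
#' @return An object of class `rate_constant_set`.
#' @export
rate_constant_set <- function(temperature_c, k_per_day, soil = "soil",
                              variant = "PHBHH9", se_k = NULL) {
  if (!is.numeric(temperature_c) || any(!is.finite(temperature_c))) {
    stop_field("temperature_c", "must be finite numeric")
  }
  if (anyDuplicated(temperature_c)) {
    stop_field("temperature_c", "temperatures must be distinct")
  }
  if (!is.numeric(k_per_day) || length(k_per_day) != length(temperature_c)) {
    stop_field("k_per_day", "must be numeric, one value per temperature")
  }
  if (any(!is.finite(k_per_day)) || any(k_per_day <= 0)) {
    stop_field("k_per_day", "all rate constants must be > 0")
  }
  if (!is.null(se_k) && length(se_k) != length(k_per_day)) {
    stop_field("se_k", "must match k_per_day in length")
  }
  structure(list(soil = soil, variant = variant,
                 temperature_c = as.numeric(temperature_c),
                 k_per_day = as.numeric(k_per_day), se_k = se_k),
            class = "rate_constant_set")
}

#' Fit the Arrhenius rate law to temperature-resolved rate constants
#'
#' Ordinary least squares of `ln k` on `1/T` (T in kelvin,
#' `T_K = T_C + 273.15`):
#' \deqn{\ln k = -\frac{E_a}{R} \frac{1}{T} + \ln A}
#' The apparent activation energy is `Ea = -slope * R` with standard error
#' `R * SE(slope)` from the residual variance on `n - 2` degrees of
#' freedom. Restricting `t_min_c`/`t_max_c` (inclusive at both bounds)
#' fits a temperature subset, as is common when the law holds only over
#' part of the measured range.
#'
#' @param rates A [rate_constant_set()].
#' @param t_min_c,t_max_c Inclusive temperature bounds (degrees C) of the
#'   points used in the regression.
#' @return An `arrhenius_fit` with elements `ea` (J mol^-1), `se_ea`,
#'   `ln_a`, `se_ln_a`, `r_squared`, `n_points`, `gas_constant`,
#'   `temp_range_used`, `soil`, `variant`. With exactly two points the
#'   standard errors are `NA` (no residual degrees of freedom); with rate
#'   constants identical at all temperatures the fit degenerates to
#'   `ea = 0` and `r_squared` is `NA` (flagged via `flat = TRUE`).
#' @examples
#' lufa22 <- rate_constant_set(c(5, 15, 25, 35),
#'                             c(0.0008, 0.0045, 0.034, 0.096),
#'                             soil = "LUFA 2.2")
#' fit_arrhenius(lufa22)
#' @export
fit_arrhenius <- function(rates, t_min_c = -Inf, t_max_c = Inf) {
  stopifnot(inherits(rates, "rate_constant_set"))
  keep <- rates$temperature_c >= t_min_c & rates$temperature_c <= t_max_c
  if (sum(keep) < 2) {
    stop_field("rates", "needs at least 2 points inside [t_min_c, t_max_c]")
  }
  tc <- rates$temperature_c[keep]
  k <- rates$k_per_day[keep]
  inv_t <- 1 / (tc + 273.15)
  ln_k <- log(k)
  n <- length(k)
  flat <- stats::var(ln_k) == 0
  if (flat) {
    fit <- list(ea = 0, se_ea = NA_real_, ln_a = mean(ln_k),
                se_ln_a = NA_real_, r_squared = NA_real_)
  } else {
    m <- stats::lm(ln_k ~ inv_t)
    # summary.lm warns on essentially perfect fits (noise-free simulations)
    sm <- suppressWarnings(summary(m))
    cf <- sm$coefficients
    slope_se <- if (n > 2) cf["inv_t", "Std. Error"] else NA_real_
    int_se <- if (n > 2) cf["(Intercept)", "Std. Error"] else NA_real_
    fit <- list(ea = -cf["inv_t", "Estimate"] * GAS_CONSTANT,
                se_ea = GAS_CONSTANT * slope_se,
                ln_a = cf["(Intercept)", "Estimate"],
                se_ln_a = int_se,
                r_squared = sm$r.squared)
  }
  structure(c(fit, list(
    n_points = n, gas_constant = GAS_CONSTANT,
    temp_range_used = range(tc), flat = flat,
    soil = rates$soil, variant = rates$variant)),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> %s / %s, %d points (%g-%g degC)\n",
              x$soil, x$variant, x$n_points,
              x$temp_range_used[1], x$temp_range_used[2]))
  cat(sprintf("  Ea  = %.1f +/- %.1f kJ mol^-1\n",
              x$ea / 1000, x$se_ea / 1000))
  cat(sprintf("  lnA = %.2f, R^2 = %.3f\n", x$ln_a, x$r_squared))
  invisible(x)
}

#' Predict a rate constant from a fitted Arrhenius law
#'
#' @param fit An `arrhenius_fit`.
#' @param temperature_c Temperature (degrees C), vectorized.
#' @return Rate constant(s) `exp(ln_a - ea / (R T_K))` in d^-1.
#' @export
predict_k <- function(fit, temperature_c) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (!is.numeric(temperature_c) || any(!is.finite(temperature_c))) {
    stop_field("temperature_c", "must be finite")
  }
  exp(fit$ln_a - fit$ea / (GAS_CONSTANT * (temperature_c + 273.15)))
}

#' Q10 temperature coefficient implied by an activation energy
#'
#' Converts an apparent activation energy into the average factor change
#' in rate per 10 degC over a stated temperature range. The default
#' `geometric-mean` method takes the geometric mean over the span:
#' `q10 = (k(T_high)/k(T_low))^(10/(t_high - t_low))` via the Arrhenius
#' law. The `per-interval` alternative averages the factor change of each
#' consecutive 10 degC interval arithmetically. The two agree closely
#' (within ~2% for Ea up to ~130 kJ mol^-1 over 0-40 degC) because the
#' Arrhenius factor varies slowly over 10 degC spans near ambient
#' temperature.
#'
#' @param ea Activation energy (J mol^-1), finite.
#' @param t_low_c,t_high_c Averaging range (degrees C); span must be at
#'   least 10 degC.
#' @param method `"geometric-mean"` (default) or `"per-interval"`.
#' @return A `q10_result` with elements `q10`, `ea`, `t_low_c`, `t_high_c`,
#'   `method`.
#' @examples
#' q10_from_ea(117000, 0, 40)
#' @export
q10_from_ea <- function(ea, t_low_c = 0, t_high_c = 40,
                        method = c("geometric-mean", "per-interval")) {
  check_scalar_num(ea, "ea")
  check_scalar_num(t_low_c, "t_low_c")
  check_scalar_num(t_high_c, "t_high_c")
  method <- match.arg(method)
  if (t_high_c < t_low_c + 10) {
    stop_field("t_high_c", "range must span at least 10 degC")
  }
  tk_low <- t_low_c + 273.15
  tk_high <- t_high_c + 273.15
  q10 <- if (method == "geometric-mean") {
    exp(ea / GAS_CONSTANT * (1 / tk_low - 1 / tk_high) *
          10 / (t_high_c - t_low_c))
  } else {
    starts <- seq(t_low_c, t_high_c - 10, by = 10) + 273.15
    mean(exp(ea / GAS_CONSTANT * (1 / starts - 1 / (starts + 10))))
  }
  structure(list(q10 = q10, ea = ea, t_low_c = t_low_c, t_high_c = t_high_c,
                 method = method),
            class = "q10_result")
}

#' @export
print.q10_result <- function(x, ...) {
  cat(sprintf("<q10_result> Q10 = %.2f (Ea = %.1f kJ mol^-1, %g-%g degC, %s)\n",
              x$q10, x$ea / 1000, x$t_low_c, x$t_high_c, x$method))
  invisible(x)
}
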