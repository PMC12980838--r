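test_that("replicate averaging gives per-time means and sample sds", {
  d <- data.frame(time_d = c(0, 0, 0), residual_percent = c(100, 98, 96))
  s <- average_replicates(d)
  expect_equal(s$mean_percent, 98)
  expect_equal(s$sd_percent, 2)  # (4 + 0 + 4)/2 = 4, sqrt = 2
  expect_equal(s$n_replicates, 3L)
  # single replicate: sd flagged missing
  s1 <- average_replicates(data.frame(time_d = c(0, 10),
                                      residual_percent = c(100, 80)))
  expect_true(all(is.na(s1$sd_percent)))
  expect_equal(s1$mean_percent, c(100, 80))
  # identical triplicates: zero variance
  d2 <- data.frame(time_d = rep(c(0, 10), each = 3),
                   residual_percent = rep(c(100, 70), each = 3))
  expect_equal(average_replicates(d2)$sd_percent, c(0, 0))
  expect_error(average_replicates(data.frame()), "dataset")
})

test_that("noise-free reference series is recovered to 1e-6 relative error", {
  # LUFA 2.4 25 degC parameters: k = 0.081/d, lag = 24 d
  s <- noise_free_series(seq(0, 70, by = 7), k = 0.081, lag = 24)
  f <- fit_shoulder_log_linear(s)
  expect_lt(abs(f$k_hat - 0.081) / 0.081, 1e-6)
  expect_lt(abs(f$lag_hat - 24) / 24, 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("a free lag on pure-exponential data is estimated near zero and insignificant", {
  s <- make_series(seq(0, 60, by = 6), 100 * exp(-0.05 * seq(0, 60, by = 6)))
  f <- fit_shoulder_log_linear(s)
  expect_lt(f$lag_hat, 1e-4)
  p_lag <- if (is.finite(f$p_lag)) f$p_lag else 1
  expect_gt(p_lag, 0.05)
})

test_that("free-lag RSS never exceeds lag-zero RSS (nested models)", {
  withr::with_seed(31, {
    for (i in 1:10) {
      d <- simulate_mass_timeseries(
        kinetic_params(100, runif(1, 0.02, 0.2), runif(1, 0, 40)),
        sampling_design(seq(0, 120, by = 12)),
        noise_model(sigma_abs = 3, seed = i))
      s <- average_replicates(d)
      f_free <- fit_shoulder_log_linear(s)
      f_zero <- fit_shoulder_log_linear(s, fix_lag_to_zero = TRUE)
      expect_lte(f_free$rss, f_zero$rss + 1e-8)
    }
  })
})

test_that("information-criterion identities hold exactly", {
  d <- simulate_mass_timeseries(kinetic_params(100, 0.1, 15),
                                sampling_design(seq(0, 60, by = 6)),
                                noise_model(sigma_abs = 2, seed = 8))
  s <- average_replicates(d)
  for (fix in c(FALSE, TRUE)) {
    f <- fit_shoulder_log_linear(s, fix_lag_to_zero = fix)
    p <- f$n_params
    n <- f$n_points
    expect_equal(f$neg2loglik, n * (log(2 * pi * f$rss / n) + 1))
    expect_equal(f$aic, f$neg2loglik + 2 * p)
    expect_equal(f$bic, f$neg2loglik + p * log(n))
    expect_false(f$chi_squared_is_rss)
    expect_gt(f$chi_squared, 0)
  }
})

test_that("chi-squared falls back to RSS when replicate sds are unusable", {
  s <- make_series(seq(0, 40, by = 10),
                   100 * exp(-0.05 * seq(0, 40, by = 10)),
                   sds = rep(NA_real_, 5), n_rep = 1L)
  f <- fit_shoulder_log_linear(s, fix_lag_to_zero = TRUE)
  expect_true(f$chi_squared_is_rss)
  expect_equal(f$chi_squared, f$rss)
})

test_that("fit agrees with a dense grid-search oracle", {
  withr::with_seed(17, {
    for (i in 1:6) {
      k <- runif(1, 0.03, 0.15); lag <- runif(1, 5, 35)
      d <- simulate_mass_timeseries(
        kinetic_params(100, k, lag),
        sampling_design(seq(0, lag + 3 / k, length.out = 10)),
        noise_model(sigma_abs = 2, seed = 100 + i))
      s <- average_replicates(d)
      f <- fit_shoulder_log_linear(s)
      k_grid <- seq(0.01, 0.25, by = 0.002)
      lag_grid <- seq(0, max(s$time_d), by = 0.5)
      g <- oracle_grid_fit(s$time_d, s$mean_percent, k_grid, lag_grid)
      expect_lte(abs(f$k_hat - g$k), 0.002 + 1e-12)
      expect_lte(abs(f$lag_hat - g$lag), 0.5 + 1e-12)
      expect_lte(f$rss, g$rss + 1e-9)
    }
  })
})

test_that("a flat no-loss series yields a finite fit with k near zero", {
  s <- make_series(c(0, 30, 60, 90, 120), rep(100, 5))
  f <- fit_shoulder_log_linear(s, fix_lag_to_zero = TRUE)
  expect_true(isTRUE(f$converged))
  expect_lt(f$k_hat, 1e-6)
  expect_true(is.finite(f$k_hat))
})

test_that("too few points for the parameter count is a validation error", {
  s2 <- make_series(c(0, 10), c(100, 60))
  expect_error(fit_shoulder_log_linear(s2), "time points")
  expect_silent(fit_shoulder_log_linear(s2, fix_lag_to_zero = TRUE))
})

test_that("lag significance rule selects the expected model variant", {
  d <- simulate_mass_timeseries(kinetic_params(100, 0.11, 13),
                                sampling_design(seq(0, 49, by = 3.5)),
                                noise_model(sigma_abs = 1, seed = 4))
  s <- average_replicates(d)
  f_free <- fit_shoulder_log_linear(s)
  f_zero <- fit_shoulder_log_linear(s, fix_lag_to_zero = TRUE)

  # clearly significant lag: free-lag model returned with both stats sets
  sel <- select_model(f_free, f_zero, alpha = 0.05)
  expect_equal(sel$variant, "free-lag")
  expect_true(sel$selection$lag_significant)
  expect_named(sel$selection$lag_zero,
               c("aic", "bic", "chi_squared", "neg2loglik", "rss"))

  # insignificant lag: zero model returned
  f_free_mod <- f_free; f_free_mod$p_lag <- 0.58
  expect_equal(select_model(f_free_mod, f_zero)$variant, "lag-fixed-zero")
  # boundary p-value counts as significant
  f_free_mod$p_lag <- 0.05
  expect_equal(select_model(f_free_mod, f_zero, alpha = 0.05)$variant,
               "free-lag")
  # missing p (degenerate free fit) falls back to the zero model
  f_free_mod$p_lag <- NA_real_
  expect_equal(select_model(f_free_mod, f_zero)$variant, "lag-fixed-zero")

  # mismatched series is rejected
  other <- fit_shoulder_log_linear(
    make_series(c(0, 5, 9, 14), c(100, 90, 70, 50)), fix_lag_to_zero = TRUE)
  expect_error(select_model(f_free, other), "same series")
})
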