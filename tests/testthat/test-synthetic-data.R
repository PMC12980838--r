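test_that("noise-free mass generator reduces to the kinetic model exactly", {
  p <- kinetic_params(100, k = 0.1, lag = 0)
  d <- simulate_mass_timeseries(p, sampling_design(c(0, 5, 10, 20)),
                                noise_model(sigma_abs = 0, seed = 1))
  expect_equal(d$residual_mass_mg, 100 * exp(-0.1 * d$time_d),
               tolerance = 1e-12)
  expect_equal(d$residual_percent, d$residual_mass_mg, tolerance = 1e-12)
  # lagged reference parameters: all replicates identical at t = 26
  d2 <- simulate_mass_timeseries(kinetic_params(100, 0.11, 13),
                                 sampling_design(c(0, 26)),
                                 noise_model(sigma_abs = 0, seed = 1))
  at26 <- d2$residual_percent[d2$time_d == 26]
  expect_equal(at26, rep(20.2454, 3), tolerance = 1e-5)
})

test_that("same seed reproduces the dataset; masses stay non-negative", {
  p <- kinetic_params(100, k = 0.05, lag = 10)
  des <- sampling_design(seq(0, 100, by = 10))
  nm <- noise_model(sigma_abs = 5, recovery_mean = 0.97, recovery_sd = 0.04,
                    seed = 123)
  d1 <- simulate_mass_timeseries(p, des, nm)
  d2 <- simulate_mass_timeseries(p, des, nm)
  expect_identical(d1, d2)
  expect_true(all(d1$residual_mass_mg >= 0))
  d3 <- simulate_mass_timeseries(p, des, noise_model(5, 0.97, 0.04, seed = 124))
  expect_false(identical(d1$residual_mass_mg, d3$residual_mass_mg))
})

test_that("sample mean of noisy masses converges to the model value", {
  p <- kinetic_params(100, k = 0.05, lag = 10)
  d <- simulate_mass_timeseries(p, sampling_design(30, replicates = 500),
                                noise_model(sigma_abs = 2, seed = 5))
  truth <- oracle_shoulder(30, 100, 0.05, 10)
  expect_lt(abs(mean(d$residual_mass_mg) - truth), 3 * 2 / sqrt(500))
})

test_that("zero-noise generation followed by fitting recovers (k, lag)", {
  withr::with_seed(21, {
    for (i in 1:5) {
      k <- runif(1, 0.02, 0.3); lag <- runif(1, 5, 50)
      d <- simulate_mass_timeseries(
        kinetic_params(100, k, lag),
        sampling_design(seq(0, lag + 4 / k, length.out = 14)),
        noise_model(sigma_abs = 0, seed = i))
      f <- fit_shoulder_log_linear(average_replicates(d))
      expect_lt(abs(f$k_hat - k) / k, 1e-6)
      expect_lt(abs(f$lag_hat - lag) / lag, 1e-6)
    }
  })
})

test_that("rate-constant generator follows the Arrhenius law", {
  flat <- simulate_rate_constants(0, log(0.05), c(5, 15, 25), seed = 1)
  expect_equal(flat$k_per_day, rep(0.05, 3), tolerance = 1e-12)
  # anchor lnA so that k(35 degC) = 0.096 with Ea = 117 kJ/mol
  ln_a <- log(0.096) + 117000 / (8.314 * 308.15)
  sim <- simulate_rate_constants(117000, ln_a, c(5, 35), seed = 1)
  expect_equal(sim$k_per_day[2], 0.096, tolerance = 1e-12)
  expect_equal(sim$k_per_day[1],
               0.096 / exp(117000 / 8.314 * (1 / 278.15 - 1 / 308.15)),
               tolerance = 1e-12)
  expect_equal(sim$k_per_day[1], 6.968294e-4, tolerance = 1e-6)
  # log-scale noise is centered on the noise-free law
  draws <- vapply(1:1000, function(s) {
    simulate_rate_constants(50000, log(0.1), 25, 0.1, seed = s)$k_per_day
  }, numeric(1))
  truth <- log(0.1) - 50000 / (8.314 * 298.15)
  expect_lt(abs(mean(log(draws)) - truth), 3 * 0.1 / sqrt(1000))
})

test_that("generator inputs are validated with the offending field named", {
  expect_error(noise_model(sigma_abs = -1, seed = 1), "sigma_abs")
  expect_error(noise_model(sigma_abs = 1, recovery_sd = -1, seed = 1),
               "recovery_sd")
  expect_error(noise_model(sigma_abs = 1), "seed")
  expect_error(sampling_design(c(0, 10, 10)), "times")
  expect_error(sampling_design(c(10, 5)), "times")
  expect_error(simulate_rate_constants(1000, 0, numeric(0), seed = 1),
               "temperatures_c")
  expect_error(simulate_peak_table(-1, 9, seed = 1), "mass_mg")
})

test_that("peak-table generator round-trips through quantification", {
  # zero polymer: analyte integrals vanish, standard stays positive
  pt0 <- simulate_peak_table(0, 9, 2, seed = 1)
  expect_equal(pt0$integral[pt0$assignment != "internal_standard"], c(0, 0))
  expect_gt(pt0$integral[pt0$assignment == "internal_standard"], 0)
  withr::with_seed(3, {
    for (i in 1:10) {
      mass <- runif(1, 0.5, 30); hh <- runif(1, 0, 20)
      std <- runif(1, 0.5, 5)
      pt <- simulate_peak_table(mass, hh, std, seed = i)
      q <- quantify_residual_mass(pt, internal_standard_spec(mass_mg = std))
      expect_equal(q$mass_mg, mass, tolerance = 1e-10)
      expect_equal(hh_mole_fraction(pt), hh, tolerance = 1e-10)
    }
  })
})

test_that("mask generator reports the exact skeleton length ground truth", {
  for (seed in 1:5) {
    m <- simulate_colonization_mask(dim_px = 128, seed = seed)
    measured_um <- attr(hyphal_length(m), "total_length_mm") * 1000
    expect_equal(measured_um, attr(m, "true_length_um"), tolerance = 1e-9)
  }
  m1 <- simulate_colonization_mask(dim_px = 128, seed = 9)
  m2 <- simulate_colonization_mask(dim_px = 128, seed = 9)
  expect_identical(m1$labels, m2$labels)
})
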