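test_that("activation energies are reproduced from the reference rate constants", {
  f22 <- fit_arrhenius(reference_rates("LUFA 2.2"))
  expect_equal(f22$ea / 1000, 117, tolerance = 0.01)
  expect_equal(f22$r_squared, 0.99, tolerance = 0.005)

  f24 <- fit_arrhenius(reference_rates("LUFA 2.4"))
  expect_equal(f24$ea / 1000, 53, tolerance = 0.01)
  expect_equal(f24$r_squared, 0.93, tolerance = 0.005)

  f6s <- fit_arrhenius(reference_rates("LUFA 6S"))
  expect_equal(f6s$ea / 1000, 63, tolerance = 0.01)
  expect_equal(f6s$r_squared, 0.83, tolerance = 0.01)

  # temperature-restricted fit, inclusive bounds
  f6s_sub <- fit_arrhenius(reference_rates("LUFA 6S"), t_min_c = 15,
                           t_max_c = 30)
  expect_equal(f6s_sub$n_points, 4L)
  expect_equal(f6s_sub$ea / 1000, 114.04, tolerance = 0.005)
  expect_equal(f6s_sub$r_squared, 0.99, tolerance = 0.005)
})

test_that("two-point fits match the closed-form activation energy", {
  rs <- rate_constant_set(c(5, 35), c(0.0008, 0.096))
  f <- fit_arrhenius(rs)
  expect_equal(f$ea, oracle_two_point_ea(35, 0.096, 5, 0.0008),
               tolerance = 1e-10)
  expect_equal(f$ea / 1000, 113.72, tolerance = 1e-4)
  expect_true(is.na(f$se_ea))  # no residual degrees of freedom
})

test_that("full-fit Ea lies between the extreme pairwise two-point values", {
  for (soil in c("LUFA 6S", "LUFA 2.4", "LUFA 2.2")) {
    rs <- reference_rates(soil)
    pairs <- utils::combn(length(rs$k_per_day), 2)
    ea_pairs <- apply(pairs, 2, function(ix) {
      oracle_two_point_ea(rs$temperature_c[ix[1]], rs$k_per_day[ix[1]],
                          rs$temperature_c[ix[2]], rs$k_per_day[ix[2]])
    })
    ea_full <- fit_arrhenius(rs)$ea
    expect_gte(ea_full, min(ea_pairs) - 1e-9)
    expect_lte(ea_full, max(ea_pairs) + 1e-9)
  }
})

test_that("noise-free simulated rates are recovered to 1e-8 relative error", {
  withr::with_seed(13, {
    for (i in 1:5) {
      ea <- runif(1, 20000, 130000); ln_a <- runif(1, 5, 40)
      sim <- simulate_rate_constants(ea, ln_a, c(5, 12, 19, 26, 33), seed = i)
      f <- fit_arrhenius(rate_constant_set(sim$temperature_c, sim$k_per_day))
      expect_lt(abs(f$ea - ea) / ea, 1e-8)
      expect_lt(abs(f$ln_a - ln_a) / abs(ln_a), 1e-8)
      # round trip: predictions reproduce the inputs
      expect_equal(predict_k(f, sim$temperature_c), sim$k_per_day,
                   tolerance = 1e-10)
    }
  })
})

test_that("flat rate data degrade gracefully to ea = 0", {
  f <- fit_arrhenius(rate_constant_set(c(5, 15, 25), rep(0.05, 3)))
  expect_equal(f$ea, 0)
  expect_true(f$flat)
  expect_true(is.na(f$r_squared))
  expect_equal(predict_k(f, c(-10, 40)), c(0.05, 0.05), tolerance = 1e-12)
})

test_that("interpolated predictions stay between bracketing rate constants", {
  f <- fit_arrhenius(reference_rates("LUFA 2.2"))
  k20 <- predict_k(f, 20)
  expect_gt(k20, 0.0045)
  expect_lt(k20, 0.034)
})

test_that("rate-set validation rejects nonpositive k and too few points", {
  expect_error(rate_constant_set(c(5, 15), c(0.1, 0)), "k_per_day")
  expect_error(rate_constant_set(c(5, 5), c(0.1, 0.2)), "temperature_c")
  expect_error(fit_arrhenius(reference_rates("LUFA 2.2"), t_min_c = 30,
                             t_max_c = 31), "at least 2")
})

test_that("Q10 behaves as the Arrhenius-implied factor change per 10 degC", {
  # zero activation energy: no temperature dependence
  expect_equal(q10_from_ea(0, 0, 40)$q10, 1)
  expect_equal(q10_from_ea(0, 0, 40, method = "per-interval")$q10, 1)
  # reference activation energies over 0-40 degC
  expect_equal(q10_from_ea(117000, 0, 40)$q10, 5.182, tolerance = 1e-3)
  expect_equal(q10_from_ea(53000, 0, 40)$q10, 2.107, tolerance = 1e-3)
  # strictly increasing in ea; methods agree within 2% up to 130 kJ/mol
  eas <- seq(10000, 130000, by = 10000)
  q_geo <- vapply(eas, function(e) q10_from_ea(e, 0, 40)$q10, numeric(1))
  q_int <- vapply(eas, function(e) {
    q10_from_ea(e, 0, 40, method = "per-interval")$q10
  }, numeric(1))
  expect_true(all(diff(q_geo) > 0))
  expect_true(all(abs(q_geo - q_int) / q_geo < 0.02))
  expect_error(q10_from_ea(50000, 0, 5), "t_high_c")
})
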