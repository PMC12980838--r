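# Independent oracles kept deliberately dumb: direct formula evaluation and
# exhaustive grid search, no shared code with the fitting path.

# residual mass by literal transcription of the model formula
oracle_shoulder <- function(t, m0, k, L) {
  m0 * exp(-k * t) * exp(k * L) / (1 + (exp(k * L) - 1) * exp(-k * t))
}

# dense (k, lag) grid search minimizing the residual sum of squares;
# after the full sweep the grid is zoomed around the incumbent a few times
# (window of +/- 2 steps, 5x finer) so the discrete argmin tracks the
# continuous minimum along the correlated (k, lag) valley
oracle_grid_fit <- function(times, means, k_grid, lag_grid, m0 = 100,
                            refine = 3) {
  sweep <- function(k_grid, lag_grid) {
    best <- list(rss = Inf)
    for (lag in lag_grid) {
      for (k in k_grid) {
        rss <- sum((means - oracle_shoulder(times, m0, k, lag))^2)
        if (rss < best$rss) best <- list(k = k, lag = lag, rss = rss)
      }
    }
    best
  }
  best <- sweep(k_grid, lag_grid)
  dk <- min(diff(k_grid)); dl <- min(diff(lag_grid))
  for (r in seq_len(refine)) {
    k_grid <- seq(max(best$k - 2 * dk, 0), best$k + 2 * dk, by = dk / 5)
    lag_grid <- seq(max(best$lag - 2 * dl, 0), best$lag + 2 * dl, by = dl / 5)
    best <- sweep(k_grid, lag_grid)
    dk <- dk / 5; dl <- dl / 5
  }
  best
}

# exact two-point activation energy (J/mol)
oracle_two_point_ea <- function(t1_c, k1, t2_c, k2) {
  8.314 * log(k1 / k2) / (1 / (t2_c + 273.15) - 1 / (t1_c + 273.15))
}

make_series <- function(times, means, sds = rep(1, length(times)),
                        n_rep = 3L) {
  structure(data.frame(time_d = times, mean_percent = means,
                       sd_percent = sds, n_replicates = n_rep),
            class = c("averaged_series", "data.frame"))
}

noise_free_series <- function(times, m0 = 100, k, lag) {
  make_series(times, oracle_shoulder(times, m0, k, lag))
}

reference_rates <- function(soil_label) {
  ref <- lufa_reference_kinetics()
  ref <- ref[ref$soil == soil_label, ]
  rate_constant_set(ref$temperature_c, ref$k_per_day, soil = soil_label)
}
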