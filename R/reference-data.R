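#' Published shoulder-log-linear fit parameters for PHBHH9 in LUFA soils
#'
#' Reference table of pseudo-first-order rate constants `k_per_day` (with
#' standard errors `se_k` and p-values `p_k`), lag-phase durations `lag_d`
#' (with `se_lag`, `p_lag`) and fit `r_squared` for PHBHH9 powder
#' biodegradation in the three standardized LUFA reference soils
#' (6S clay, 2.4 loam, 2.2 sandy loam) across incubation temperatures of
#' 5-35 degC. Rows with `lag_d = 0` are treatments where the lag term was
#' not statistically significant (`p_lag > 0.05`) and was therefore fixed
#' at zero; p-values printed as upper bounds are stored at that bound.
#'
#' These values serve two roles in the package: as ground-truth parameters
#' for the synthetic-data generator, and as the rate-constant inputs to the
#' Arrhenius analysis.
#'
#' @return A data.frame with columns `soil`, `temperature_c`, `variant`,
#'   `k_per_day`, `se_k`, `p_k`, `lag_d`, `se_lag`, `p_lag`, `r_squared`.
#' @examples
#' head(lufa_reference_kinetics())
#' @export
lufa_reference_kinetics <- function() {
  path <- system.file("extdata", "lufa_phbhh9_kinetics.csv",
                      package = "phbdeg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
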