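# File schemas. All CSVs use explicit headers, UTF-8, period decimal
# separator; temperatures are degrees C in files (kelvin only internally).

MASS_CSV_COLUMNS <- c("soil", "temperature_c", "variant", "time_d",
                      "replicate", "initial_mass_mg", "residual_mass_mg",
                      "residual_percent")
RATE_CSV_COLUMNS <- c("soil", "variant", "temperature_c", "k_per_day")
PEAK_CSV_COLUMNS <- c("assignment", "integral", "protons_per_unit")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_field(what, paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Write / read replicate-level residual-mass observations
#'
#' Schema: `soil, temperature_c, variant, time_d, replicate,
#' initial_mass_mg, residual_mass_mg, residual_percent`.
#'
#' @param dataset A `residual_mass_dataset` (or conforming data.frame).
#' @param path CSV path.
#' @export
write_mass_csv <- function(dataset, path) {
  check_columns(dataset, MASS_CSV_COLUMNS, "dataset")
  utils::write.csv(as.data.frame(dataset)[MASS_CSV_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_mass_csv
#' @export
read_mass_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, MASS_CSV_COLUMNS, basename(path))
  bad <- which(!is.finite(df$residual_mass_mg) | df$residual_mass_mg < 0)
  if (length(bad)) {
    stop_field(basename(path), sprintf(
      "negative or non-finite residual_mass_mg at row(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  structure(df, class = c("residual_mass_dataset", "data.frame"))
}

#' Write / read temperature-resolved rate constants
#'
#' Schema: `soil, variant, temperature_c, k_per_day` (optionally `se_k`).
#'
#' @param rates Data.frame of rate constants.
#' @param path CSV path.
#' @export
write_rates_csv <- function(rates, path) {
  check_columns(rates, RATE_CSV_COLUMNS, "rates")
  utils::write.csv(rates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, RATE_CSV_COLUMNS, basename(path))
  df
}

#' Write / read an NMR peak table
#'
#' Schema: `assignment, integral, protons_per_unit`.
#'
#' @param peaks A [peak_table()].
#' @param path CSV path.
#' @export
write_peaks_csv <- function(peaks, path) {
  check_columns(peaks, PEAK_CSV_COLUMNS, "peaks")
  utils::write.csv(as.data.frame(peaks)[PEAK_CSV_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, PEAK_CSV_COLUMNS, basename(path))
  peak_table(df$assignment, df$integral, df$protons_per_unit)
}

#' Serialize a kinetic or Arrhenius fit (or Q10 result) to JSON
#'
#' All fields of the object are written, plus, for kinetic fits, fitted
#' curve samples at the observed times.
#'
#' @param fit A `kinetic_fit`, `arrhenius_fit` or `q10_result`.
#' @param path Output JSON path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Flat one-row summary of a selected kinetic fit
#'
#' Mirrors the columns of the published parameter table: `soil`,
#' `temperature_c`, `variant`, `k`, `se_k`, `p_k`, `lag`, `se_lag`,
#' `p_lag`, `r_squared`, plus the selected model variant.
#'
#' @param fit A converged `kinetic_fit`.
#' @param soil,temperature_c,variant Treatment metadata.
#' @export
kinetic_fit_row <- function(fit, soil = NA, temperature_c = NA,
                            variant = NA) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!isTRUE(fit$converged)) {
    return(data.frame(soil = soil, temperature_c = temperature_c,
                      variant = variant, model = "fit-failed",
                      k = NA_real_, se_k = NA_real_, p_k = NA_real_,
                      lag = NA_real_, se_lag = NA_real_, p_lag = NA_real_,
                      r_squared = NA_real_, stringsAsFactors = FALSE))
  }
  data.frame(soil = soil, temperature_c = temperature_c, variant = variant,
             model = fit$variant, k = fit$k_hat, se_k = fit$se_k,
             p_k = fit$p_k, lag = fit$lag_hat, se_lag = fit$se_lag,
             p_lag = fit$p_lag, r_squared = fit$r_squared,
             stringsAsFactors = FALSE)
}
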