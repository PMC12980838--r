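#' Configuration for the end-to-end analysis pipeline
#'
#' @param masses_csv Optional path to a replicate-level residual-mass CSV
#'   (see [write_mass_csv()] for the schema). When absent, the kinetics
#'   stage is skipped.
#' @param rates_csv Optional path to a rate-constant CSV (see
#'   [write_rates_csv()]). When absent, rate constants are taken from the
#'   kinetics stage.
#' @param alpha Lag-phase significance level (default 0.05).
#' @param t_min_c,t_max_c Inclusive temperature bounds for the Arrhenius
#'   fits.
#' @param q10_t_low,q10_t_high,q10_method Q10 averaging range and method.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed documents the provenance of simulated
#'   inputs).
#' @param verbose Print per-treatment progress.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(masses_csv = NULL, rates_csv = NULL,
                            alpha = 0.05, t_min_c = -Inf, t_max_c = Inf,
                            q10_t_low = 0, q10_t_high = 40,
                            q10_method = "geometric-mean",
                            out_dir = tempfile("phbdeg-run-"), seed = 1,
                            verbose = TRUE) {
  check_scalar_num(alpha, "alpha", lower = 0, allow_zero = FALSE)
  if (alpha >= 1) stop_field("alpha", "must be < 1")
  for (p in c(masses_csv, rates_csv)) {
    if (!file.exists(p)) stop_field("input paths", paste("no such file:", p))
  }
  if (is.null(masses_csv) && is.null(rates_csv)) {
    stop_field("input paths", "need masses_csv and/or rates_csv")
  }
  structure(list(masses_csv = masses_csv, rates_csv = rates_csv,
                 alpha = alpha, t_min_c = t_min_c, t_max_c = t_max_c,
                 q10_t_low = q10_t_low, q10_t_high = q10_t_high,
                 q10_method = q10_method, out_dir = out_dir,
                 seed = check_seed(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Composes the stages: per-treatment shoulder-log-linear fits with
#' lag-phase model selection (when mass data are given), then per
#' soil/variant Arrhenius fits and Q10 conversion over the fitted (or
#' supplied) rate constants. Writes a parameter-table CSV
#' (`kinetic_fits.csv`), a rate-constant CSV (`rate_constants.csv`), an
#' Arrhenius/Q10 CSV (`arrhenius_fits.csv`) and a JSON manifest recording
#' package version, seed, configuration and a content hash of the
#' configuration. A treatment whose fit fails is reported in the manifest
#' and in the returned `failures` list; it never silently disappears and
#' never aborts the other treatments.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list with `kinetic_fits` (named list of
#'   selected `kinetic_fit`s), `fit_table` (data.frame),
#'   `arrhenius` (named list of `arrhenius_fit`), `q10` (named list of
#'   `q10_result`), `failures`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))

  kinetic_fits <- list()
  failures <- list()
  fit_table <- NULL
  rates <- NULL

  if (!is.null(config$masses_csv)) {
    masses <- read_mass_csv(config$masses_csv)
    groups <- split(masses,
                    interaction(masses$soil, masses$temperature_c,
                                masses$variant, drop = TRUE))
    rows <- list()
    for (g in groups) {
      label <- sprintf("%s @%g degC %s", g$soil[1], g$temperature_c[1],
                       g$variant[1])
      res <- tryCatch({
        series <- average_replicates(g)
        sel <- select_model(
          fit_shoulder_log_linear(series, fix_lag_to_zero = FALSE),
          fit_shoulder_log_linear(series, fix_lag_to_zero = TRUE),
          alpha = config$alpha)
        say("fitted %s: model %s, k = %.4g", label, sel$variant, sel$k_hat)
        sel
      }, error = function(e) e)
      if (inherits(res, "error") ||
          (inherits(res, "kinetic_fit") && !isTRUE(res$converged))) {
        msg <- if (inherits(res, "error")) conditionMessage(res)
               else res$diagnostics$message
        say("FAILED %s: %s", label, msg)
        failures[[label]] <- msg
        next
      }
      kinetic_fits[[label]] <- res
      rows[[label]] <- kinetic_fit_row(res, soil = g$soil[1],
                                       temperature_c = g$temperature_c[1],
                                       variant = g$variant[1])
    }
    if (length(rows)) {
      fit_table <- do.call(rbind, c(rows, make.row.names = FALSE))
      utils::write.csv(fit_table, file.path(config$out_dir, "kinetic_fits.csv"),
                       row.names = FALSE)
      rates <- data.frame(soil = fit_table$soil, variant = fit_table$variant,
                          temperature_c = fit_table$temperature_c,
                          k_per_day = fit_table$k, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(config$rates_csv)) {
    rates <- read_rates_csv(config$rates_csv)
  }

  arrhenius <- list()
  q10 <- list()
  if (!is.null(rates)) {
    rates <- rates[is.finite(rates$k_per_day) & rates$k_per_day > 0, ]
    write_rates_csv(rates, file.path(config$out_dir, "rate_constants.csv"))
    arr_rows <- list()
    for (grp in split(rates, interaction(rates$soil, rates$variant,
                                         drop = TRUE))) {
      label <- sprintf("%s %s", grp$soil[1], grp$variant[1])
      res <- tryCatch({
        rs <- rate_constant_set(grp$temperature_c, grp$k_per_day,
                                soil = grp$soil[1], variant = grp$variant[1])
        fit <- fit_arrhenius(rs, t_min_c = config$t_min_c,
                             t_max_c = config$t_max_c)
        qr <- q10_from_ea(fit$ea, config$q10_t_low, config$q10_t_high,
                          method = config$q10_method)
        say("Arrhenius %s: Ea = %.1f kJ/mol, Q10 = %.2f",
            label, fit$ea / 1000, qr$q10)
        list(fit = fit, q10 = qr)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        say("FAILED Arrhenius %s: %s", label, conditionMessage(res))
        failures[[paste("arrhenius", label)]] <- conditionMessage(res)
        next
      }
      arrhenius[[label]] <- res$fit
      q10[[label]] <- res$q10
      arr_rows[[label]] <- data.frame(
        soil = grp$soil[1], variant = grp$variant[1],
        ea_kj_per_mol = res$fit$ea / 1000,
        se_ea_kj_per_mol = res$fit$se_ea / 1000,
        ln_a = res$fit$ln_a, r_squared = res$fit$r_squared,
        n_points = res$fit$n_points, q10 = res$q10$q10,
        stringsAsFactors = FALSE)
    }
    if (length(arr_rows)) {
      utils::write.csv(do.call(rbind, c(arr_rows, make.row.names = FALSE)),
                       file.path(config$out_dir, "arrhenius_fits.csv"),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    package = "phbdeg",
    version = as.character(utils::packageVersion("phbdeg")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(config),
    n_treatments_in = length(kinetic_fits) +
      sum(!startsWith(names2(failures), "arrhenius")),
    n_fitted = length(kinetic_fits),
    failures = failures,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  structure(list(kinetic_fits = kinetic_fits, fit_table = fit_table,
                 arrhenius = arrhenius, q10 = q10, failures = failures,
                 manifest = manifest, out_dir = config$out_dir),
            class = "pipeline_result")
}

names2 <- function(x) if (is.null(names(x))) character(0) else names(x)

# md5 of the canonical JSON serialization of the config (out_dir and
# verbosity excluded: they do not affect the numbers)
config_hash <- function(config) {
  essential <- unclass(config)
  essential$out_dir <- NULL
  essential$verbose <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(essential, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(tools::md5sum(tmp))
}
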