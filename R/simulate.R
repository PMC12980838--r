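#' Sampling design of a soil incubation
#'
#' @param times Ordered sampling days (d), strictly increasing, first may be
#'   0.
#' @param replicates Number of replicate incubation vials per time point
#'   (default 3, the usual triplicate design; each vial is sacrificed at its
#'   sampling time).
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(times, replicates = 3) {
  if (!is.numeric(times) || length(times) == 0 || any(!is.finite(times))) {
    stop_field("times", "must be a non-empty finite numeric vector")
  }
  if (any(times < 0)) stop_field("times", "must be >= 0")
  if (any(diff(times) <= 0)) stop_field("times", "must be strictly increasing")
  check_scalar_num(replicates, "replicates", lower = 1)
  if (replicates != round(replicates)) {
    stop_field("replicates", "must be an integer")
  }
  structure(list(times = as.numeric(times),
                 replicates = as.integer(replicates)),
            class = "sampling_design")
}

#' Measurement-noise model for simulated residual masses
#'
#' Additive Gaussian noise on the mass scale plus an optional multiplicative
#' extraction-recovery factor drawn once per sample (per vial), emulating
#' per-sample solvent extraction before gravimetric/NMR quantification.
#' Simulated masses are truncated at zero. The default recovery of
#' 0.97 +/- 0.04 matches spike-recovery levels typical of Soxhlet extraction
#' of polyesters from soil.
#'
#' @param sigma_abs Additive noise standard deviation, in the units of the
#'   initial mass (>= 0).
#' @param recovery_mean Mean multiplicative extraction recovery (default 1:
#'   no recovery loss).
#' @param recovery_sd Recovery standard deviation (>= 0, default 0).
#' @param seed Integer random seed (mandatory).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_abs = 0, recovery_mean = 1, recovery_sd = 0,
                        seed) {
  check_scalar_num(sigma_abs, "sigma_abs", lower = 0)
  check_scalar_num(recovery_mean, "recovery_mean", lower = 0)
  check_scalar_num(recovery_sd, "recovery_sd", lower = 0)
  seed <- check_seed(seed)
  structure(list(sigma_abs = sigma_abs, recovery_mean = recovery_mean,
                 recovery_sd = recovery_sd, seed = seed),
            class = "noise_model")
}

#' Simulate a replicate-level residual-mass time series
#'
#' Generates destructive-sampling observations from the shoulder-log-linear
#' model: for each (time, replicate) vial, residual mass equals a per-vial
#' recovery draw times the model value plus additive Gaussian noise,
#' truncated below at zero. Identical arguments (including the seed inside
#' `noise`) give identical datasets.
#'
#' @param params A [kinetic_params()] object (ground truth).
#' @param design A [sampling_design()] object.
#' @param noise A [noise_model()] object.
#' @param soil,temperature_c,variant Treatment metadata carried through to
#'   the dataset.
#' @return A `residual_mass_dataset`: a data.frame with columns `soil`,
#'   `temperature_c`, `variant`, `time_d`, `replicate`, `initial_mass_mg`,
#'   `residual_mass_mg`, `residual_percent`, plus the treatment and ground
#'   truth stored as attributes.
#' @examples
#' d <- simulate_mass_timeseries(
#'   kinetic_params(m0 = 100, k = 0.11, lag = 13),
#'   sampling_design(times = seq(0, 56, by = 7)),
#'   noise_model(sigma_abs = 2, recovery_mean = 0.97, recovery_sd = 0.04,
#'               seed = 1))
#' head(d)
#' @export
simulate_mass_timeseries <- function(params, design, noise,
                                     soil = "synthetic", temperature_c = 25,
                                     variant = "PHBHH9") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(design, "sampling_design"),
            inherits(noise, "noise_model"))
  n_t <- length(design$times)
  n_r <- design$replicates
  time_d <- rep(design$times, each = n_r)
  truth <- shoulder_mass(time_d, params$m0, params$k, params$lag)
  obs <- withr::with_seed(noise$seed, {
    recovery <- if (noise$recovery_sd > 0 || noise$recovery_mean != 1) {
      stats::rnorm(length(time_d), noise$recovery_mean, noise$recovery_sd)
    } else {
      rep(1, length(time_d))
    }
    eps <- if (noise$sigma_abs > 0) {
      stats::rnorm(length(time_d), 0, noise$sigma_abs)
    } else {
      0
    }
    pmax(recovery * truth + eps, 0)
  })
  out <- data.frame(
    soil = soil, temperature_c = temperature_c, variant = variant,
    time_d = time_d,
    replicate = rep(seq_len(n_r), times = n_t),
    initial_mass_mg = params$m0,
    residual_mass_mg = obs,
    residual_percent = 100 * obs / params$m0,
    stringsAsFactors = FALSE)
  structure(out, class = c("residual_mass_dataset", "data.frame"),
            params = params, design = design, noise = noise)
}

#' Simulate temperature-resolved rate constants from an Arrhenius law
#'
#' Draws rate constants `k(T) = exp(ln A - Ea / (R T_K) + eps)` with
#' `eps ~ Normal(0, lognormal_sd)` and `T_K = T_degC + 273.15`.
#'
#' @param ea_j_per_mol Apparent activation energy (J mol^-1).
#' @param ln_pre_exponential Natural log of the pre-exponential factor
#'   (k in d^-1).
#' @param temperatures_c Incubation temperatures (degrees C), non-empty.
#' @param lognormal_sd Standard deviation of the log-scale noise (>= 0).
#' @param seed Integer random seed.
#' @param soil,variant Metadata labels.
#' @return A data.frame with columns `soil`, `variant`, `temperature_c`,
#'   `k_per_day`.
#' @export
simulate_rate_constants <- function(ea_j_per_mol, ln_pre_exponential,
                                    temperatures_c, lognormal_sd = 0, seed,
                                    soil = "synthetic", variant = "PHBHH9") {
  check_scalar_num(ea_j_per_mol, "ea_j_per_mol")
  check_scalar_num(ln_pre_exponential, "ln_pre_exponential")
  if (!is.numeric(temperatures_c) || length(temperatures_c) == 0 ||
      any(!is.finite(temperatures_c))) {
    stop_field("temperatures_c", "must be a non-empty finite numeric vector")
  }
  check_scalar_num(lognormal_sd, "lognormal_sd", lower = 0)
  seed <- check_seed(seed)
  t_k <- temperatures_c + 273.15
  ln_k <- ln_pre_exponential - ea_j_per_mol / (GAS_CONSTANT * t_k)
  if (lognormal_sd > 0) {
    ln_k <- ln_k + withr::with_seed(
      seed, stats::rnorm(length(t_k), 0, lognormal_sd))
  }
  data.frame(soil = soil, variant = variant,
             temperature_c = as.numeric(temperatures_c),
             k_per_day = exp(ln_k), stringsAsFactors = FALSE)
}

#' Simulate a qNMR peak table with known ground truth
#'
#' Builds a three-peak table (internal standard, 3-HB diagnostic, 3-HH
#' diagnostic) whose noise-free integrals are proportional to moles times
#' protons per unit, so that [quantify_residual_mass()] and
#' [hh_mole_fraction()] round-trip the inputs exactly at zero noise.
#' Noise is multiplicative Gaussian on each integral (factor
#' `1 + Normal(0, integral_noise_sd)`, truncated at 0), reflecting
#' integration error roughly proportional to peak size.
#'
#' @param mass_mg Polymer mass in the measured tube (mg, >= 0).
#' @param hh_mole_percent 3-HH comonomer content (mole percent, 0-100).
#' @param standard_mass_mg Internal standard mass (mg, > 0).
#' @param integral_noise_sd Relative integral noise (>= 0).
#' @param seed Integer random seed.
#' @param standard A [internal_standard_spec()].
#' @param monomers A [monomer_spec()].
#' @return A [peak_table()].
#' @export
simulate_peak_table <- function(mass_mg, hh_mole_percent,
                                standard_mass_mg = 2, integral_noise_sd = 0,
                                seed, standard = internal_standard_spec(
                                  mass_mg = standard_mass_mg),
                                monomers = monomer_spec()) {
  check_scalar_num(mass_mg, "mass_mg", lower = 0)
  check_scalar_num(hh_mole_percent, "hh_mole_percent", lower = 0)
  if (hh_mole_percent > 100) stop_field("hh_mole_percent", "must be <= 100")
  check_scalar_num(standard_mass_mg, "standard_mass_mg", lower = 0,
                   allow_zero = FALSE)
  check_scalar_num(integral_noise_sd, "integral_noise_sd", lower = 0)
  seed <- check_seed(seed)
  f_hh <- hh_mole_percent / 100
  # mmol of repeat units from the number-average unit mass
  unit_mass <- (1 - f_hh) * monomers$hb_unit_mass + f_hh * monomers$hh_unit_mass
  n_total <- mass_mg / unit_mass
  n_hb <- (1 - f_hh) * n_total
  n_hh <- f_hh * n_total
  n_std <- standard$mass_mg / standard$molar_mass
  # arbitrary absolute scale; only ratios matter downstream
  integrals <- c(internal_standard = n_std * standard$protons_used,
                 hb_diagnostic = n_hb * 3,
                 hh_diagnostic = n_hh * 3) * 100
  if (integral_noise_sd > 0) {
    integrals <- withr::with_seed(seed, {
      pmax(integrals * (1 + stats::rnorm(3, 0, integral_noise_sd)), 0)
    })
  }
  peak_table(assignment = names(integrals),
             integral = unname(integrals),
             protons_per_unit = c(standard$protons_used, 3L, 3L))
}

#' Simulate a colonization label mask with known hyphal length
#'
#' Draws straight hyphal segments (horizontal, vertical, or diagonal) in
#' disjoint bands of the image, plus rectangular dense-colony and hole
#' blocks, so the ground-truth skeleton length is known exactly from the
#' segment geometry: a segment of `n` pixels contributes `n - 1` steps of
#' 1 px (axis-aligned) or `sqrt(2)` px (diagonal).
#'
#' @param dim_px Image size (pixels per side of the square mask).
#' @param n_hyphae Number of hyphal segments.
#' @param segment_px Pixel count of each segment.
#' @param n_colony,colony_px Number and side length of dense-colony blocks.
#' @param n_hole,hole_px Number and side length of hole blocks.
#' @param pixel_size_um Pixel edge length (micrometres per pixel).
#' @param seed Integer random seed.
#' @return A [colonization_mask()] with attribute `true_length_um`, the
#'   exact total hyphal length in micrometres.
#' @export
simulate_colonization_mask <- function(dim_px = 256, n_hyphae = 8,
                                       segment_px = 40, n_colony = 2,
                                       colony_px = 20, n_hole = 1,
                                       hole_px = 12, pixel_size_um = 1,
                                       seed) {
  seed <- check_seed(seed)
  stopifnot(dim_px >= 4, segment_px >= 2, segment_px <= dim_px,
            n_hyphae >= 0, n_colony >= 0, n_hole >= 0)
  labels <- matrix(0L, dim_px, dim_px)
  true_len <- 0
  withr::with_seed(seed, {
    # hyphae: one segment per row band so segments never touch
    if (n_hyphae > 0) {
      band <- max(3L, dim_px %/% (2L * n_hyphae))
      for (i in seq_len(n_hyphae)) {
        r0 <- (i - 1L) * band + 2L
        if (r0 + segment_px >= dim_px) break
        ori <- sample(c("h", "v", "d"), 1)
        c0 <- sample.int(dim_px - segment_px, 1)
        idx <- switch(ori,
          h = cbind(r0, c0 + seq_len(segment_px) - 1L),
          v = cbind(r0 + seq_len(min(segment_px, band - 2L)) - 1L, c0),
          d = cbind(r0 + seq_len(min(segment_px, band - 2L)) - 1L,
                    c0 + seq_len(min(segment_px, band - 2L)) - 1L))
        # vertical/diagonal segments are clipped to the band so bands stay
        # disjoint; the truth accounts for the clipped length
        n_px <- nrow(idx)
        if (ori == "d") {
          true_len <- true_len + (n_px - 1) * sqrt(2) * pixel_size_um
        } else {
          true_len <- true_len + (n_px - 1) * pixel_size_um
        }
        labels[idx] <- 1L
      }
    }
    # blocks go only on skeleton-free intact area so the length truth holds
    place_block <- function(labels, side, value) {
      for (tries in 1:50) {
        r <- sample.int(dim_px - side, 1)
        c <- sample.int(dim_px - side, 1)
        block <- labels[r:(r + side - 1L), c:(c + side - 1L)]
        if (all(block == 0L)) {
          labels[r:(r + side - 1L), c:(c + side - 1L)] <- value
          break
        }
      }
      labels
    }
    for (i in seq_len(n_colony)) labels <- place_block(labels, colony_px, 2L)
    for (i in seq_len(n_hole)) labels <- place_block(labels, hole_px, 3L)
  })
  mask <- colonization_mask(labels, pixel_size_um = pixel_size_um)
  attr(mask, "true_length_um") <- true_len
  mask
}
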