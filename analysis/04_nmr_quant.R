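#!/usr/bin/env Rscript
# qNMR quantification layer: simulates peak tables for a 9 mol% 3-HH
# copolymer along a biodegradation course (decreasing residual mass at
# constant comonomer composition, 2% integral noise), quantifies residual
# mass against the DMB internal standard, and tracks the recovered 3-HH
# mole percent. Tubes below 0.67 mg/mL are flagged low-concentration.
#
# Writes: results/nmr_quant.csv

suppressPackageStartupMessages(library(phbdeg))
dir.create("results", showWarnings = FALSE)

initial_mg <- 20
course <- seq(1, 0, by = -0.1)  # fraction of polymer remaining
rows <- lapply(seq_along(course), function(i) {
  true_mg <- initial_mg * course[i]
  pt <- simulate_peak_table(true_mg, hh_mole_percent = 9,
                            standard_mass_mg = 2,
                            integral_noise_sd = 0.02, seed = 300 + i)
  q <- quantify_residual_mass(pt, tube_volume_ml = 10)
  data.frame(
    true_mass_mg = true_mg,
    quantified_mass_mg = q$mass_mg,
    residual_pct = as.numeric(percent_residual(q$mass_mg, initial_mg)),
    hh_mol_pct = if (true_mg > 0) hh_mole_fraction(pt) else NA_real_,
    low_concentration = "low_concentration" %in% q$flags)
})
out <- do.call(rbind, rows)
write.csv(out, "results/nmr_quant.csv", row.names = FALSE)

ok <- !is.na(out$hh_mol_pct) & !out$low_concentration
cat(sprintf("quantified %d tubes; mass error (not low-conc): max %.2f%%\n",
            nrow(out),
            100 * max(abs(out$quantified_mass_mg - out$true_mass_mg)[ok] /
                        out$true_mass_mg[ok])))
cat(sprintf("3-HH mol%% across the course: %.2f-%.2f (truth 9.00), stable as expected\n",
            min(out$hh_mol_pct[ok]), max(out$hh_mol_pct[ok])))
cat(sprintf("%d tube(s) flagged below 0.67 mg/mL\n", sum(out$low_concentration)))
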