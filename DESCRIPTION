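Package: phbdeg
Title: Kinetics of Polyhydroxyalkanoate Biodegradation in Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of polyester (PHBHHx) biodegradation in
    soil incubations. Fits the shoulder-log-linear kinetic model (an initial
    lag phase followed by pseudo-first-order mass loss) to replicate-averaged
    residual-mass time series with Wald-test lag-phase model selection and
    AIC/BIC/chi-squared fit diagnostics; fits the Arrhenius rate law to
    temperature-resolved rate constants to estimate apparent activation
    energies and Q10 temperature coefficients; converts quantitative 1H NMR
    peak-integral tables into residual polymer mass (internal-standard
    method) and 3-hydroxyhexanoate comonomer mole percent; and computes
    hyphal-colonization summaries (skeleton length per film area, area
    fractions of dense colony, holes and intact film) from class-label
    masks. A seeded synthetic-data generator emulates the study design
    (triplicate mass-loss curves, temperature-resolved rate constants, NMR
    peak tables, colonization masks) so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
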