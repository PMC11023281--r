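Package: koalapk
Title: Non-Compartmental Pharmacokinetics for a Paracetamol Dosing Study in
    Koalas
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-compartmental pharmacokinetic analysis of plasma
    concentration-time profiles (terminal-slope estimation, log-linear
    trapezoidal AUC and AUMC with extrapolation to infinity, mean residence
    time, apparent clearance and volume, and absorption rate by the method
    of residuals), together with the companion calculations of a
    single/multiple-dose paracetamol study in koalas: multiple-dose
    superposition and accumulation, therapeutic-window residence time,
    plasma-protein-binding percentages from ultrafiltration assays,
    microsomal substrate-depletion intrinsic clearance, and exact
    matched-pairs Wilcoxon signed-rank testing. Includes a synthetic-data
    generator emulating the study design (one-compartment first-order
    absorption, lognormal assay noise, LLOQ censoring) for validation and
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
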