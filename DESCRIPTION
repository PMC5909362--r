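Package: mammodose
Title: Average Absorbed Breast Dose (2ABD) Calculation for Mammography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the average absorbed breast dose (2ABD), a mammography
    dose index evaluable from the acquisition parameters recorded for every
    exposure (tube voltage, tube load, compressed breast thickness,
    anode-filter combination).  Provides tube-output calibration (linear
    kerma-per-mAs fits against kVp), estimation of effective energy
    absorption coefficients from exponential attenuation series in
    water-equivalent material, closed-form incident air kerma and 2ABD
    evaluation with first-order uncertainty propagation, reference average
    glandular dose (AGD) calculators in the Dance (g, c, s) and Wu (DgN)
    formalisms from user-supplied coefficient grids, exam ingestion from
    DICOM headers or CSV batches, synthetic measurement generators for
    validation, and batch dose-audit reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
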