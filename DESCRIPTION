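Package: metaboscreen
Title: Untargeted Dried-Blood-Spot Metabolomics Screening and
    Pyrophosphatase Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for untargeted direct-infusion
    high-resolution mass spectrometry screening of dried blood spots:
    adduct-aware annotation of centroided peak lists against a metabolite
    reference within a ppm tolerance, summing of adduct intensities into one
    value per metabolite annotation, Z-scoring of patient samples against
    within-run controls, dual-proband elevation filtering, and pathway /
    pyrophosphate-formation flagging of candidate biomarkers of inborn
    errors of metabolism. Also implements the companion functional-assay
    computations (inorganic-pyrophosphatase specific activity from
    colorimetric plate data with a phosphate standard curve; galactolytic
    capacity from extracellular-acidification traces) and a synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
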