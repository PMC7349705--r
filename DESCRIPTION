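Package: telodyn
Title: Telomere Length Quantification from Southern Blot Densitometry and
    Blood-and-Muscle Telomere Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the blood-and-muscle telomere model: densitometric
    quantification of mean terminal restriction fragment (TRF) length from
    Southern-blot lane profiles (molecular-weight ladder power-law
    calibration, windowed OD-weighted mean, duplicate reconciliation,
    intraclass-correlation reliability), descriptive telomere dynamics for
    paired leukocyte (LTL) and skeletal-muscle (MTL) telomere lengths
    (LTL/MTL ratio, age slopes, age- and sex-adjusted means), and gated
    SNP-association analysis under an additive model with Hardy-Weinberg
    quality control and a pairwise epistasis scan.  A synthetic-data module
    simulates gel lanes, ladders, membranes and genotyped cohorts with known
    ground truth so every stage of the pipeline can be exercised and
    validated without raw gel images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
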