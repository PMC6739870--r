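Package: mgsbias
Title: Multiplicative Bias Estimation and Calibration for Marker-Gene and
    Metagenomic Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models taxonomic bias in marker-gene and shotgun metagenomic
    sequencing (MGS) as a composition-independent multiplication of the true
    relative abundances by taxon-specific relative efficiencies. Provides a
    compositional least-squares estimator of bias (or of differential bias
    between protocols) from mock-community or spike-in control samples,
    including controls with only partial taxon overlap, with bootstrap
    geometric standard errors; calibration of measurements by compositional
    division; decomposition of total-protocol bias into per-step biases from
    multi-entry-point experiments; 16S copy-number bias prediction and
    correction; pairwise bias and noise summary statistics; and a simulator
    of even-mixture and spike-in control designs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    graphics,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
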