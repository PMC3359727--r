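Package: CrystalCast
Title: Protein Crystallizability Prediction from Characterization Experiments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts raw protein-characterization experiments (differential
    scanning fluorimetry melt curves, size-exclusion chromatograms, dynamic
    light scattering peak tables, expression yield, SDS-PAGE and limited
    proteolysis) plus sequence features into standardized summary statistics,
    and feeds them to a recursive regression partition tree that predicts a
    0-6 crystallographic diffraction score with a decision path and
    prioritization suggestions. Includes Boltzmann melt-curve fitting,
    Gaussian peak deconvolution, hydrodynamic radius to molecular weight
    conversion, an XML interchange format, a CART-style tree trainer, and
    synthetic-data generators emulating every supported raw format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    xml2,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
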