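Package: leafspec
Title: Leaf-Level Hyperspectral Reflectance Analysis for Forest CO2
    Enrichment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for leaf-level hyperspectral reflectance campaigns in
    free-air CO2 enrichment (FACE) experiments: reading and stitching
    multi-detector field-spectroradiometer spectra, resampling to a common
    1 nm grid, absolute-reflectance panel calibration, a synthetic
    leaf-spectra campaign simulator with hierarchical (tree / tree-by-date /
    leaf) variance structure, vegetation indices (NDVI, MCARI, PRI, PSRI,
    NDNI, NDLI, NDWI, NPQI) and integrated reflectance, principal component
    analysis, partial least squares discriminant analysis with
    cross-validated component tuning and cumulative wavelength importance,
    and nested random-intercept linear mixed models estimated by REML with
    Satterthwaite degrees of freedom.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
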