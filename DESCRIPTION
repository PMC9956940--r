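Package: hsiwound
Title: Hyperspectral Planimetry of Pressure Injuries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures pressure-injury wound area from 16-band visible-range
    hyperspectral image cubes. Reads ENVI and multi-band TIFF cubes, applies
    white-reference reflectance calibration, separates wound from healthy
    skin by unsupervised k-means clustering of pixel spectra, and reports
    both the bedside length-by-width (LW rule) bounding-box area and a
    morphology-cleaned planimetric area. Includes the method-agreement
    statistics used to compare nurse and machine measurements (Pearson and
    Spearman correlation, single-measure and variance-component intraclass
    correlation, unweighted and weighted kappa), a bundled 30-case clinical
    comparison table, and a synthetic hyperspectral wound-phantom generator
    with exactly known ground-truth area for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
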