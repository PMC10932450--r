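Package: libstissue
Title: Tissue Discrimination from Laser-Induced Breakdown Spectroscopy Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating tissue types in mandibular
    bone-infiltrating head and neck cancer from single-shot laser-induced
    breakdown spectroscopy (LIBS) emission spectra. Covers spectrum I/O and an
    element-tagged wavelength-bin catalog, spectrometer-baseline subtraction,
    base-peak normalization and per-bin peak-area integration, summed Ca/K/Na
    electrolyte features, nonparametric group comparison (Kruskal-Wallis with
    Dunn's post hoc test), pairwise ROC analysis with DeLong confidence
    intervals and Youden-index cutoffs, ordered four-class metric scales for Ca
    and K, and reference-fixed principal component analysis. Includes a
    synthetic single-shot spectrum generator whose per-class summed peak areas
    follow log-normal distributions calibrated from published median and
    interquartile-range summaries, so every stage of the pipeline is testable
    without access to the original patient spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
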