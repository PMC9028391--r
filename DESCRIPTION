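Package: thyromsi
Title: MALDI Mass Spectrometry Imaging Classification of Thyroid Fine-Needle Aspirates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the cytomolecular classification of
    thyroid nodules from MALDI mass spectrometry imaging (MALDI-MSI) of
    fine-needle aspiration (FNA) needle washes. Provides a reproducible
    synthetic MSI cohort generator (linear-positive-mode protein spectra,
    3000-15000 m/z, three spectral phenotypes), imzML 1.1 input/output,
    spectral preprocessing (Savitzky-Golay smoothing, SNIP baseline
    subtraction, TIC normalization, peak picking and binning), a 3-class
    L1-penalized multinomial classifier with cross-validated penalty
    selection, per-nodule diagnosis by overall-average, region-of-interest
    and pixel-by-pixel aggregation with Youden-index and double-cutoff
    threshold estimation, a three-level gray-zone diagnostic triage, and
    diagnostic-performance reporting with exact binomial confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
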