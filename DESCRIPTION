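Package: tracerkit
Title: Global Stable-Isotope Tracing Metabolomics by Targeted
    Isotopologue Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metabolome-wide quantification of stable-isotope (13C) labeling
    from LC-MS data. Given centroided MS1 runs of unlabeled control and
    labeled samples plus a metabolite annotation table, the package computes
    theoretical isotopologue m/z series, extracts and detects isotopologue
    peaks with signal-to-noise and peak-shape (PPC) filtering, corrects for
    natural 13C abundance by non-negative least squares, estimates and
    subtracts isotope contamination from unlabeled controls, and reports mass
    isotopomer distributions (MIDs). Downstream tools quantify labeling
    extents and first-order labeling rates, cluster labeling profiles, build
    FDR-controlled metabolite-metabolite correlation networks, run
    hypergeometric pathway enrichment, and evaluate false-positive rates on
    unlabeled samples. A ground-truthed synthetic LC-MS generator supports
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    mzR,
    pracma,
    purrr,
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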