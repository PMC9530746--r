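Package: chnis
Title: Cold-Hot Nature Identification of Herbal Medicines from HPLC Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a Mahalanobis distance metric over high-performance liquid
    chromatography (HPLC) fingerprints by combining a pairwise-constraint class
    scatter with a patch-alignment geometric similarity term, and uses the
    learned metric in a distance-weighted retrieval classifier that converts
    the nearest reference herbs into a cold-nature probability. Includes the
    full evaluation tool-chain (leave-one-out stability, repeated stratified
    split extrapolation, ROC/AUC, confusion-matrix metrics, parameter sweeps),
    Pearson-correlation and plain-Euclidean retrieval baselines, and a
    synthetic chromatogram generator for end-to-end testing when no measured
    fingerprints are available.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
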