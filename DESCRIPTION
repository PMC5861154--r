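Package: refstab
Title: Reference Gene Stability Evaluation for qRT-PCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate qRT-PCR reference (housekeeping) genes by
    expression stability using four established estimators - the comparative
    delta-Ct method, geNorm M-values with stepwise exclusion and pairwise
    variation, a model-based intra-/intergroup variance decomposition of the
    NormFinder type, and BestKeeper descriptive statistics with index
    correlations - and aggregates the per-method ranks into a geometric-mean
    consensus ranking. Includes Ct table input/output with
    technical-replicate collapsing, standard-curve amplification-efficiency
    fitting, a stratified analysis driver for multi-factor designs
    (treatment by age by tissue), and a synthetic Ct-data generator with
    known ground-truth stability for method validation, plus a command-line
    interface for analysis, simulation and recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
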