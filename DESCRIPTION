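Package: gmrank
Title: Gene Master Regulator Ranking from Replicated Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the Gene Master Regulator (GMR) of a cell phenotype
    from probe-level expression data with biological replicates. Computes
    the chi-square mid-interval corrected Relative Expression Variation
    (REV) pooled over redundant probes, the Relative Expression Stability
    (RES), gene-specific fold-change cut-offs and regulation calls, the
    Weighted Pathway Regulation (WPR), all-pairs expression coordination on
    the log2 scale, and the Gene Commanding Height (GCH) hierarchy whose
    top gene is the GMR. Ships a synthetic-data harness with a planted
    regulator and simulated perturbations so that the central claim
    (higher GCH implies larger perturbation consequences) is testable
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
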