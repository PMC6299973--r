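Package: ecconsensus
Title: Consensus and Benchmarking of Multi-Tool Metabolic Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes heterogeneous enzyme (EC number) and membrane-transporter
    annotations produced by different genome annotation tools into one exchange
    format, then quantifies their overlap and agreement: support partitions of
    gene-EC annotations, pairwise tool agreement, EC-set coverage, gold-standard
    precision and recall for the union and intersection of every tool
    combination, and transporter substrate-specificity rankings. Ships a
    synthetic multi-tool annotation generator with known ground truth so every
    statistic can be exercised and calibrated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
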