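Package: bsmapr
Title: Bisulfite-Treated Read Mapping and Methylation Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps bisulfite-treated single-end sequencing reads against a
    reference genome using the three-letter alphabet reduction strategy:
    reads and genome are reduced to a three-letter alphabet (C-to-T and
    G-to-A), aligned in two (directional) or four (non-directional) passes
    with a complete ungapped search or gapped global/local dynamic
    programming, then post-processed in the original four-letter alphabet
    with asymmetric bisulfite-aware mismatch counting to remove false
    positives and ambiguous reads. Supports whole-genome (WGBS) and reduced
    representation (RRBS) libraries, with in-silico restriction digestion
    and fragment-size masking for the latter, per-cytosine methylation-level
    estimation in CpG/CHG/CHH contexts, a seeded bisulfite read simulator
    with ground-truth ledgers and 3'-biased positional error decay, SAM
    output, and precision/recall/F1 evaluation against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
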