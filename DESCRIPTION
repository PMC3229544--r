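Package: probeRank
Title: Probe-Level Rank-Based Differential Expression for Oligonucleotide Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric differential expression analysis applied directly to
    probe-level measurements of oligonucleotide expression arrays. Probes are
    mapped to a transcriptome with an ungapped exact-match rule (>= 22 nt),
    normalized by relative ranking within each array, and tested per probe with
    an exact Mann-Whitney test across a panel of two-group comparisons. Each
    probe receives an H/L/E expression string; probes are clustered by string
    identity and expression profiles are attributed to transcripts with a
    hypergeometric over-representation tail, controlled by Benjamini-Hochberg
    FDR. Includes a gene-list enrichment statistic based on summed
    hypergeometric densities, a delta-delta-Ct fold-change utility, and a
    synthetic-data generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
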