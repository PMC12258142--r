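Package: svconsensus
Title: Consensus Structural-Variant and Copy-Number Calls from Multiple Callers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges somatic structural-variant (SV) calls from multiple callers
    into high-confidence consensus SVs, and derives a genome-wide consensus
    copy-number profile with per-caller concordance metrics (bias and
    volatility). SV calls are standardized to oriented breakend pairs, related
    by matching chromosomes, orientations and a positional window, clustered by
    single linkage, and collapsed to mode positions with caller-support
    confidence. Copy-number segments are padded, overlap-divided, partitioned
    at all caller boundaries, averaged per interval, and smoothed. Includes
    readers and writers for VCF breakend and symbolic SV records, BEDPE and
    SEG-like segment tables, circos-style track export, tumor purity/ploidy
    selection, a command-line interface, and a seeded simulator of multi-caller
    outputs for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
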