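Package: lilyprint
Title: Parent-of-Origin Expression and Methylation Analysis for Water-Lily Endosperm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls maternally and paternally expressed imprinted genes (MEGs and
    PEGs) from allele-resolved RNA-seq counts of reciprocal interspecies crosses,
    using a bias-adjusted exact test with imprinting-factor, cis-effect-factor,
    maternal-fraction and cross-replicate consistency gates; corrects endosperm
    maternal-allele counts for assumed whole-seed (maternal tissue) transcript
    contamination; calls parent-of-origin differentially methylated regions from
    allele-resolved per-cytosine methylation calls in 300-bp windows with
    context-specific difference thresholds and Fisher's exact tests; computes
    metagene methylation profiles and conversion rates; and simulates
    allele-resolved expression tables and paired parental methylomes with known
    ground truth so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
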