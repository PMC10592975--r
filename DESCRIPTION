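Package: snotarget
Title: Consensus Differential Expression and Orphan C/D-Box snoRNA Target
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream inference pipeline for orphan C/D-box snoRNA target
    studies in isogenic deletion models of the Prader-Willi locus. Provides
    low-count filtering and consensus differential-expression calling across
    isogenic genetic backgrounds, deletion models and statistical designs;
    permutation nulls for k-way gene-list overlaps; a minimal hypergeometric
    over-representation statistic with fold enrichment; consolidation of
    sliding-window RNA-RNA interaction predictions into binding events via a
    consecutive-window filter; covariate-matched control gene-list sampling
    (length, GC content, expression) and targeting-enrichment statistics with
    empirical p-values; genomic feature composition of binding events
    (5'UTR/CDS/3'UTR/intron/junction); and binding-position distributions
    relative to snoRNA C/C'/D/D' boxes and antisense elements. A fully seeded
    synthetic-data module generates every input with planted structure,
    including a SNORD116/SNORD115 locus fixture, so that all statistics can be
    validated by planted-truth recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
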