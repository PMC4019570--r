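Package: ionsnp
Title: Duplicate Filtering, Homopolymer Gap Repair and SNP-Call Evaluation
    for Ion Semiconductor Sequencing
Version: 0.1.0
Authors@R:
    person("Ion", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Preprocessing and evaluation tools for SNP calling from ion
    semiconductor (flow-based) single-end sequencing data. Implements
    alignment-score-aware duplicate read filtering (reads piled on a shared
    5' mapped coordinate are thinned by an AS-tag threshold, always keeping
    the best read per pile), pileup-level repair of improper homopolymer
    indels (gaps occurring at low frequency in homopolymer context are
    excised or the read dropped), a minimal pileup-frequency SNP caller, a
    call-set evaluation suite (FP/FN rates against control sets, Ti/Tv,
    het/hom, db rate, overlap, consensus, depth-saturation curves), and a
    deterministic simulator of variable-length single-end reads with
    PCR-duplicate piles and homopolymer over/undercall errors plus truth
    files, so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    GenomicRanges,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
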