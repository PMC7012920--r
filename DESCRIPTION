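Package: poolmap
Title: Bulked-Segregant QTL-Seq Mapping with an In-Silico F2 Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping trait loci in F2 populations by pooled
    sequencing (QTL-Seq / bulked segregant analysis). Computes per-site
    SNP-indices for two phenotype-extreme pools against either parent,
    applies co-segregation filtering, averages delta(SNP-index) in sliding
    windows, attaches null-simulation confidence envelopes, and extracts
    refined candidate intervals that are annotated against gene models and
    an anthocyanin-pathway gene table. A companion simulator generates
    recombinant gametes, F2 genotypes, a multi-locus epistatic trait
    (one dominant suppressor plus five recessive direct loci), extreme
    pools, and pooled allele-depth read counts, so every pipeline stage is
    testable without external data. Also includes a single-marker LOD
    linkage scan and a pool-contrast read-depth scan that flags candidate
    insertions as localized depth collapses in one pool.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
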