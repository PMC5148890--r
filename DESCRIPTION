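Package: transcat
Title: Consensus Coding Transcriptomes from Multiple De Novo Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a non-redundant consensus coding transcriptome from the
    outputs of two or more independent de novo transcriptome assemblers.
    Assemblies are name-harmonized so provenance stays traceable, strictly
    redundant transcripts are removed within each assembly by greedy
    clustering at 100% local identity over the full shorter sequence,
    survivors are pooled, open reading frames of at least 100 amino acids
    are extracted, and the coding sequences are clustered again at 98%
    identity to yield one representative CDS per cluster.  Clusters are
    classified by which assemblers contributed members, per-assembler CDS
    extension statistics are computed, and evaluation utilities provide
    assembly statistics (N50 and friends), annotatability counts from
    tabular similarity-search hits, a coverage-ratio sweep, and a
    reference-recovery comparison.  A deterministic synthetic-data module
    generates truth transcriptomes with planted ORFs and mock assembler
    outputs with controlled duplication, truncation, substitution error,
    dropout and artifact transcripts, together with a manifest that makes
    every downstream count checkable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
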