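Package: comparome
Title: Comparative Yeast Genomics with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pairwise structural-variant classification and tallying from
    whole-genome alignments, Ty retrotransposon annotation with viability
    calls, pangenome-based gene-loss calling, and a multi-criterion
    introgression-candidate ORF filter for comparative analyses of yeast
    assemblies. A synthetic-genome generator plants every feature class the
    analyses detect (substitution divergence along a strain tree, the five
    structural-variant types including terminal translocations, Ty elements
    in all states, clade-restricted gene absences, and diverged ORFs) and
    emits machine-readable truth tables, so the whole pipeline is testable
    without external data. Alignment is self-contained: maximal-exact-match
    seeding with collinear chaining, plus affine-gap local alignment for
    ORF-level comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
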