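Package: linforge
Title: Incremental Genome Similarity Encoding with Life Identification
    Numbers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Assigns hierarchical Life Identification Numbers (LINs) to
    prokaryotic genome assemblies by combining fast MinHash sketch search
    with a single precise fragment-based average nucleotide identity (ANI)
    computation per added genome, stores genomes, taxonomy, schemes, LINs
    and ANI records in an embedded relational store, and infers complete
    pairwise ANI similarity matrices from the assigned LINs. Includes a
    seeded synthetic-genome and clade simulator, complete-linkage
    clustering and Mantel matrix-correlation utilities for evaluating
    inferred matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
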