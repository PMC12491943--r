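Package: micromask
Title: Detection, Annotation and Masking of Microbial-Like Regions in
    Eukaryotic Reference Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects regions of eukaryotic genome assemblies that attract
    microbial sequence, annotates them with their most abundant source taxa,
    and masks or extracts them. Contaminant-source genomes are fragmented
    into fixed-length sliding-window pseudo-reads, placed on the target with
    a deterministic seed-and-extend aligner retaining multimapping hits, and
    covered intervals are merged into extended BED regions with supporting
    read counts and ranked taxon attributions. Downstream validation tools
    include breadth-of-coverage and per-contig fraction summaries, a
    random-placement permutation test for read/region intersection
    enrichment with an analytic expectation oracle, and MinHash sketching
    with Mash distances and principal-coordinate embedding to contrast the
    k-mer composition of exogenous and endogenous segments. A synthetic
    fixture generator plants divergent microbial inserts at known
    coordinates so the whole workflow is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
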