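Package: xgrkit
Title: Ontology Enrichment, Variant-to-Gene Linking and Gene Subnetwork
    Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A programmable toolkit for exploring genomic summary data with
    gene-centric knowledgebases.  Provides six analysers: ontology enrichment
    for gene lists, GWAS SNP sets and genomic regions (one-sided Fisher's
    exact test with Z-scores, Haldane-corrected odds ratios, Woolf confidence
    intervals and Benjamini-Hochberg FDR); SNP- and region-to-gene linking via
    linkage-disequilibrium expansion, genomic proximity, promoter-capture
    Hi-C, activity-by-contact enhancer maps and e/pQTL evidence with 1-10
    gene scores and per-evidence provenance; and gene-subnetwork
    identification by a prize-collecting Steiner tree heuristic with a
    degree-preserving permutation significance test.  All knowledgebases are
    plain-text (GMT/TSV/BED) and a synthetic fixture generator makes every
    analyser runnable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
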