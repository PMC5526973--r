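Package: phylocontrast
Title: Phylogenetic-Contrast Screening of Transcription-Factor Target Genes
Version: 0.1.0
Authors@R: person("phylocontrast", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for identifying genes differentially regulated under a
    focal condition relative to several comparison conditions, as used in
    phylogenetic-contrast overexpression screens. Implements the multi-stage
    candidate screen (unidirectional entry criterion, twofold mean-versus-mean
    filter, reference-list classification), small-sample statistics (Welch and
    Student t-tests, Benjamini-Hochberg FDR, a heteroscedastic unequal-n
    effect-size correlation r, noncentral-t post-hoc power, min fold-change,
    Mann-Whitney U), comparative-Ct qPCR quantification with multi-reference
    normalization, promoter extraction and exact IUPAC motif scanning with
    background-normalized read coverage, scored PPI network statistics and GO
    hypergeometric enrichment with a doubled-FDR adjustment, and seeded
    synthetic-data generators with planted ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
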