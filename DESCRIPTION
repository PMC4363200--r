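Package: SporeCall
Title: Two-Stage Self-Training GHMM Gene Prediction for Fungal Genomes
    from Assembled RNA-Seq Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-coding genes in compact, gene-dense fungal
    genomes using assembled, genome-aligned RNA-seq transcripts.  A
    generalised hidden Markov model (GHMM) is first self-trained on and
    decoded over virtually spliced transcript sequences; a second,
    genome-space GHMM with an explicit intron sub-model (donor, branch
    point and acceptor weighted array matrices) is then trained from the
    stage-one genes and decoded over selected genomic regions under
    transcript-derived splice-boundary constraints.  Predictions from the
    two stages are merged and passed through false-positive filters; the
    package also reports suspected merged (fused) transcript assemblies,
    forces "dubious" gene calls in otherwise gene-free transcripts, and
    computes Burset-Guigo sensitivity and specificity at the nucleotide,
    exon, intron and gene level.  A seeded synthetic-genome generator
    reproduces the transcript-assembly pathologies the method targets so
    that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
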