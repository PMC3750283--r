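Package: venomtx
Title: Venom-Gland Transcriptome Analysis of Toxin Expression,
    Heterozygosity and Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for snake venom-gland transcriptomes built
    around annotated full-length transcripts: merging of 3'-overlapping
    read pairs into composite reads, clustering of toxin transcripts at a
    nucleotide-divergence threshold, read mapping and cluster-level
    expression quantification, pileup-based heterozygous SNP calling with
    allele-frequency and coverage filters, synonymous/nonsynonymous
    annotation and toxin-versus-nontoxin heterozygosity comparison, and
    codon site-model (M0, M1a, M2a, M7, M8) likelihood-ratio tests for
    positive selection on fixed trees. A synthetic-data generator produces
    transcriptomes, diploid read sets and codon alignments with known
    ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
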