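Package: modpolisher
Title: Reference-Guided Correction of Modification-Mediated Errors in
    Nanopore Draft Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-assembly polisher for nanopore draft genomes that targets
    systematic mismatch errors caused by DNA modifications untrained in the
    basecalling model. Closely related genomes are selected by MinHash
    sketch identity and filtered by fragment average nucleotide identity
    (ANI) and average structural identity (ASI); read and homolog
    alignments are summarised into a per-locus pileup of allele counts and
    mean basecall quality; loci with discordant, low-quality read pileups
    are corrected to the homolog consensus only when the homologs are
    fully conserved (or 80 percent conserved inside a user-supplied
    modified motif). Includes a modified-motif extractor, a synthetic
    truth-set generator for end-to-end validation, and a Phred-scaled
    assembly quality evaluator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: minimap2, samtools
Config/testthat/edition: 3
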