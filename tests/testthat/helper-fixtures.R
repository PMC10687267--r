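# Shared fixture builders. Everything is generated in code; no binary files.

ACGT <- c("A", "C", "G", "T")

random_genome <- function(n, gc = 0.5) {
    paste(sample(ACGT, n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# substitute `rate` of positions (or the given 1-based positions) with a
# different base; returns the mutated string
mutate_seq <- function(seq, rate = NULL, positions = NULL) {
    ch <- strsplit(seq, "")[[1]]
    if (is.null(positions))
        positions <- which(stats::runif(length(ch)) < rate)
    if (length(positions)) {
        shift <- sample.int(3L, length(positions), replace = TRUE)
        code <- match(ch[positions], ACGT)
        ch[positions] <- ACGT[((code - 1L + shift) %% 4L) + 1L]
    }
    paste(ch, collapse = "")
}

revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# independent oracle: distinct canonical k-mers of a sequence, enumerated
# with substring + Biostrings reverse complement (no rolling hash involved)
canonical_kmers <- function(seq, k) {
    n <- nchar(seq)
    if (n < k) return(character(0))
    km <- substring(seq, seq_len(n - k + 1L), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(km)))
    unique(pmin(km, rc))
}

# brute-force Jaccard over complete canonical k-mer sets
brute_jaccard <- function(a, b, k = 21L) {
    sa <- canonical_kmers(a, k)
    sb <- canonical_kmers(b, k)
    length(intersect(sa, sb)) / length(union(sa, sb))
}

mash_identity_from_jaccard <- function(j, k = 21L) {
    if (j <= 0) return(0)
    min(1, max(0, 1 + log(2 * j / (1 + j)) / k))
}

# hand-built SAM fixtures -------------------------------------------------

qstring <- function(phred) intToUtf8(phred + 33L)

sam_record <- function(qname, pos, seq, qual = "*", flag = 0L,
                       cigar = paste0(nchar(seq), "M"), contig = "ctg",
                       mapq = 60L) {
    paste(qname, flag, contig, pos, mapq, cigar, "*", 0, 0, seq, qual,
          sep = "\t")
}

write_sam <- function(records, contig = "ctg", len = 100L,
                      path = tempfile(fileext = ".sam")) {
    writeLines(c("@HD\tVN:1.6",
                 sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
                 records), path)
    path
}

# a PileupMatrix built directly from per-locus specifications, for
# threshold unit tests (the SAM path is exercised elsewhere)
toy_matrix <- function(draft_seq, read_counts, hom_counts, mean_qual) {
    L <- nchar(draft_seq)
    stopifnot(ncol(read_counts) == L, ncol(hom_counts) == L,
              length(mean_qual) == L)
    rownames(read_counts) <- rownames(hom_counts) <- ACGT
    depth <- colSums(read_counts)
    structure(list(contig_id = "toy", draft_seq = draft_seq,
                   read_counts = read_counts, hom_counts = hom_counts,
                   qual_sum = mean_qual * depth,
                   perr_sum = 10^(-mean_qual / 10) * depth,
                   n_homolog_tracks = max(colSums(hom_counts))),
              class = "PileupMatrix")
}

# small, fast synthetic truth set for unit tests (acceptance uses defaults)
small_truth_set <- function(seed = 1L, dir = tempfile("fix"), ...) {
    args <- list(length = 8000L, n_modified = 8L, n_decoys = 4L,
                 n_homologs = 5L, depth = 25, read_length = 500L,
                 seed = seed, out_dir = dir)
    args[names(list(...))] <- list(...)
    do.call(simulate_truth_set, args)
}
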