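#' Generate a synthetic truth set for end-to-end validation
#'
#' Builds a complete, self-consistent fixture emulating the error structure
#' of a modification-affected nanopore draft: a truth genome with planted
#' motif occurrences, a draft carrying substitution errors at a subset of
#' motif loci (the "modified" loci), reads whose pileups at those loci are
#' discordant with depressed basecall quality, homolog genomes at a
#' controlled SNP divergence that carry the truth allele at every modified
#' locus, and strain-variant *decoy* loci where the homologs unanimously
#' disagree with the draft while the reads confirm it at high quality — the
#' case a specific polisher must leave alone.
#'
#' All randomness flows from `seed`; two runs with the same parameters emit
#' byte-identical files. Reads are emitted both as FASTQ and as a
#' pre-aligned coordinate-sorted SAM with exact CIGARs, so downstream tests
#' never need an external aligner.
#'
#' Per-locus read behaviour: at background loci a read shows the draft base
#' with probability `1 - read_error` (else a uniformly random other base)
#' at Phred quality uniform in `bg_qual`; at modified loci it shows the
#' draft's error base with probability `1 - minor_fraction` and the truth
#' base otherwise, at quality uniform in `mod_qual`. Draft errors follow a
#' fixed transversion table (A>C, C>A, G>T, T>G); decoy homolog alleles
#' follow the transition table (A>G, G>A, C>T, T>C).
#'
#' @param length genome length in bases (default 50000).
#' @param gc GC fraction of the random genome (default 0.5).
#' @param motif planted motif, plain ACGT (default `"GCAGC"`).
#' @param mod_offset 0-based offset of the modified base inside the motif
#'   (default 2, the central base of a pentamer).
#' @param n_modified number of modified loci (default 40).
#' @param n_decoys number of strain-variant decoy loci (default 20).
#' @param n_homologs number of homolog genomes (default 10).
#' @param homolog_snp_rate per-base substitution rate of each homolog vs
#'   the truth (default 0.005, i.e. ~99.5% ANI).
#' @param depth mean read depth (default 30).
#' @param read_length read length in bases (default 3000); reads are
#'   clipped at contig ends so coverage stays uniform.
#' @param read_error background per-base read error rate (default 0.01).
#' @param minor_fraction fraction of reads showing the truth allele at a
#'   modified locus (default 0.3, i.e. expected discordancy 0.3).
#' @param mod_qual,bg_qual inclusive integer Phred ranges for modified and
#'   background loci (defaults 6–12 and 20–30).
#' @param frac_reverse fraction of reads on the reverse strand
#'   (default 0.5).
#' @param seed integer seed.
#' @param out_dir optional directory; when given, writes `truth.fa`,
#'   `draft.fa`, `reads.fastq`, `reads.sam`, `homolog_XX.fa`,
#'   `homolog_XX.sam` and `truth_table.tsv`.
#' @return object of class `SyntheticTruthSet`: list with `truth_genome`,
#'   `draft_genome`, `modified_loci` (data.frame `position` 0-based,
#'   `truth_allele`, `draft_allele`), `decoy_variant_loci` (data.frame
#'   `position`, `draft_allele`, `homolog_allele`), `homolog_genomes`
#'   (character vector), `files` (named paths or `NULL`) and `parameters`.
#' @export
simulate_truth_set <- function(length = 50000L, gc = 0.5, motif = "GCAGC",
                               mod_offset = 2L, n_modified = 40L,
                               n_decoys = 20L, n_homologs = 10L,
                               homolog_snp_rate = 0.005, depth = 30,
                               read_length = 3000L, read_error = 0.01,
                               minor_fraction = 0.3, mod_qual = c(6L, 12L),
                               bg_qual = c(20L, 30L), frac_reverse = 0.5,
                               seed = 1L, out_dir = NULL) {
    stopifnot(length >= 1000L, nchar(motif) >= 1L,
              mod_offset >= 0L, mod_offset < nchar(motif))
    motif <- toupper(motif)
    if (grepl("[^ACGT]", motif))
        stop("generator motif must be plain ACGT")
    w <- nchar(motif)
    margin <- max(200L, read_length %/% 10L)
    if (n_modified * 20L + 2L * margin > length)
        stop("infeasible parameters: genome too short for ", n_modified,
             " well-separated modified loci")
    set.seed(seed)

    TV <- c(A = "C", C = "A", G = "T", T = "G")  # truth -> draft error
    TS <- c(A = "G", G = "A", C = "T", T = "C")  # draft -> decoy allele

    truth_ch <- sample(BASES, length, replace = TRUE,
                       prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

    # collect motif occurrences inside the margins, planting extras if the
    # random background does not supply enough
    truth <- paste(truth_ch, collapse = "")
    occ <- as.integer(gregexpr(motif, truth, fixed = TRUE)[[1]])
    occ <- occ[occ > 0L & occ > margin & occ + w - 1L <= length - margin]
    # drop overlapping occurrences so chosen sites never collide
    if (length(occ) > 1L) occ <- occ[c(TRUE, diff(occ) >= 20L)]
    tries <- 0L
    while (length(occ) < n_modified && tries < 10000L) {
        p <- sample(seq.int(margin + 1L, length - margin - w), 1L)
        if (all(abs(p - occ) >= 20L)) {
            truth_ch[p:(p + w - 1L)] <- strsplit(motif, "")[[1]]
            occ <- sort(c(occ, p))
        }
        tries <- tries + 1L
    }
    if (length(occ) < n_modified)
        stop("infeasible parameters: could not obtain ", n_modified,
             " motif sites")
    mod_occ <- sort(occ[sample.int(length(occ), n_modified)])
    mod_pos1 <- mod_occ + mod_offset
    truth_allele <- truth_ch[mod_pos1]
    error_allele <- unname(TV[truth_allele])

    draft_ch <- truth_ch
    draft_ch[mod_pos1] <- error_allele

    # decoy loci: outside every motif occurrence, away from modified loci
    blocked <- logical(length)
    for (p in occ) blocked[p:(p + w - 1L)] <- TRUE
    for (p in mod_pos1) blocked[max(1L, p - 10L):min(length, p + 10L)] <- TRUE
    pool <- which(!blocked)
    pool <- pool[pool > margin & pool <= length - margin]
    if (length(pool) < n_decoys)
        stop("infeasible parameters: not enough free positions for ",
             n_decoys, " decoy loci")
    decoy_pos1 <- sort(pool[sample.int(length(pool), n_decoys)])
    decoy_allele <- unname(TS[draft_ch[decoy_pos1]])

    protected <- c(mod_pos1, decoy_pos1)
    homologs <- character(n_homologs)
    for (i in seq_len(n_homologs)) {
        h <- .mutate_homolog(truth_ch, homolog_snp_rate, protected)
        h[decoy_pos1] <- decoy_allele
        homologs[i] <- paste(h, collapse = "")
    }

    reads <- .simulate_reads(draft_ch, truth_ch, mod_pos1, depth,
                             read_length, read_error, minor_fraction,
                             mod_qual, bg_qual, frac_reverse)

    truth_table <- rbind(
        data.frame(position = mod_pos1 - 1L,
                   class = rep("modified", length(mod_pos1)),
                   truth_allele = truth_allele,
                   draft_allele = error_allele,
                   homolog_allele = truth_allele,
                   stringsAsFactors = FALSE),
        data.frame(position = decoy_pos1 - 1L,
                   class = rep("decoy", length(decoy_pos1)),
                   truth_allele = truth_ch[decoy_pos1],
                   draft_allele = draft_ch[decoy_pos1],
                   homolog_allele = decoy_allele,
                   stringsAsFactors = FALSE))
    truth_table <- truth_table[order(truth_table$position), ]
    rownames(truth_table) <- NULL

    params <- list(length = length, gc = gc, motif = motif,
                   mod_offset = mod_offset, n_modified = n_modified,
                   n_decoys = n_decoys, n_homologs = n_homologs,
                   homolog_snp_rate = homolog_snp_rate, depth = depth,
                   read_length = read_length, read_error = read_error,
                   minor_fraction = minor_fraction, mod_qual = mod_qual,
                   bg_qual = bg_qual, frac_reverse = frac_reverse,
                   seed = seed)

    files <- NULL
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        fp <- function(x) file.path(out_dir, x)
        .write_fasta(c(ctg1 = paste(truth_ch, collapse = "")), fp("truth.fa"))
        .write_fasta(c(ctg1 = paste(draft_ch, collapse = "")), fp("draft.fa"))
        .write_read_fastq(reads, fp("reads.fastq"))
        .write_read_sam(reads, "ctg1", length, fp("reads.sam"))
        hom_fa <- hom_sam <- character(n_homologs)
        for (i in seq_len(n_homologs)) {
            id <- sprintf("homolog_%02d", i)
            hom_fa[i] <- fp(paste0(id, ".fa"))
            hom_sam[i] <- fp(paste0(id, ".sam"))
            .write_fasta(stats::setNames(homologs[i], id), hom_fa[i])
            .write_hom_sam(id, homologs[i], "ctg1", length, hom_sam[i])
        }
        utils::write.table(truth_table, fp("truth_table.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        files <- list(truth = fp("truth.fa"), draft = fp("draft.fa"),
                      reads_fastq = fp("reads.fastq"),
                      reads_sam = fp("reads.sam"),
                      homolog_fastas = hom_fa, homolog_sams = hom_sam,
                      truth_table = fp("truth_table.tsv"))
    }

    structure(list(truth_genome = paste(truth_ch, collapse = ""),
                   draft_genome = paste(draft_ch, collapse = ""),
                   modified_loci = truth_table[truth_table$class == "modified",
                                               c("position", "truth_allele",
                                                 "draft_allele")],
                   decoy_variant_loci =
                       truth_table[truth_table$class == "decoy",
                                   c("position", "draft_allele",
                                     "homolog_allele")],
                   homolog_genomes = homologs,
                   truth_table = truth_table,
                   files = files, parameters = params),
              class = "SyntheticTruthSet")
}

#' @export
print.SyntheticTruthSet <- function(x, ...) {
    cat(sprintf(
        "SyntheticTruthSet: %d bp, %d modified + %d decoy loci, %d homolog(s), seed %d\n",
        nchar(x$truth_genome), nrow(x$modified_loci),
        nrow(x$decoy_variant_loci), length(x$homolog_genomes),
        x$parameters$seed))
    invisible(x)
}

# substitutions at snp_rate everywhere except protected 1-based positions
.mutate_homolog <- function(truth_ch, snp_rate, protected) {
    h <- truth_ch
    if (snp_rate > 0) {
        snp <- which(stats::runif(length(truth_ch)) < snp_rate)
        snp <- setdiff(snp, protected)
        if (length(snp)) {
            shift <- sample.int(3L, length(snp), replace = TRUE)
            code <- match(h[snp], BASES)
            h[snp] <- BASES[((code - 1L + shift) %% 4L) + 1L]
        }
    }
    h
}

#' Derive a homolog genome from the truth
#'
#' Applies substitutions at `snp_rate` (never at `protected` loci) and
#' replaces each structural-variant block with random sequence, which
#' drives ASI down measurably while leaving ANI of the intact fragments
#' high. Uses the current RNG state; call `set.seed()` first for
#' reproducibility.
#'
#' @param truth truth genome (character string).
#' @param snp_rate per-base substitution probability.
#' @param sv_blocks optional data.frame with 0-based `position` and
#'   `length` columns; blocks must not overlap.
#' @param protected integer vector of 0-based positions that must keep the
#'   truth allele.
#' @return homolog genome as a character string.
#' @export
homolog_model <- function(truth, snp_rate, sv_blocks = NULL,
                          protected = integer(0)) {
    truth_ch <- strsplit(.as_seqs(truth)[[1]], "")[[1]]
    h <- .mutate_homolog(truth_ch, snp_rate, as.integer(protected) + 1L)
    if (!is.null(sv_blocks) && nrow(sv_blocks) > 0L) {
        ord <- order(sv_blocks$position)
        sv_blocks <- sv_blocks[ord, , drop = FALSE]
        ends <- sv_blocks$position + sv_blocks$length
        if (any(sv_blocks$position[-1] < utils::head(ends, -1)))
            stop("sv_blocks overlap")
        if (any(ends > length(h))) stop("sv_block extends past the genome")
        for (i in seq_len(nrow(sv_blocks))) {
            at <- (sv_blocks$position[i] + 1L):ends[i]
            h[at] <- sample(BASES, length(at), replace = TRUE)
        }
    }
    paste(h, collapse = "")
}

#' Sample one locus's read pileup
#'
#' Draws `depth` (base, Phred) pairs from the generator's per-locus model:
#' background loci show the truth base with probability `1 - error_rate`
#' (else a random other base) at quality uniform in `bg_qual`; modified
#' loci show the draft's error base with probability `1 - minor_fraction`
#' and the truth base otherwise, at quality uniform in `mod_qual`, so the
#' expected discordancy is `minor_fraction` and the expected mean quality
#' is `mean(mod_qual)`. Uses the current RNG state.
#'
#' @param class `"background"` or `"modified"`.
#' @param depth number of read bases to draw.
#' @param truth_base the truth allele at the locus.
#' @param error_base the draft's error allele (modified loci only;
#'   defaults to the generator's transversion of `truth_base`).
#' @param error_rate,minor_fraction,mod_qual,bg_qual see
#'   [simulate_truth_set()].
#' @return data.frame with columns `base` and `phred`.
#' @export
read_pileup_model <- function(class = c("background", "modified"), depth,
                              truth_base = "A", error_base = NULL,
                              error_rate = 0.01, minor_fraction = 0.3,
                              mod_qual = c(6L, 12L), bg_qual = c(20L, 30L)) {
    class <- match.arg(class)
    stopifnot(depth >= 1L, truth_base %in% BASES)
    if (class == "background") {
        err <- stats::runif(depth) < error_rate
        base <- rep(truth_base, depth)
        if (any(err)) {
            shift <- sample.int(3L, sum(err), replace = TRUE)
            code <- match(truth_base, BASES)
            base[err] <- BASES[((code - 1L + shift) %% 4L) + 1L]
        }
        phred <- sample(seq.int(bg_qual[1], bg_qual[2]), depth,
                        replace = TRUE)
    } else {
        if (is.null(error_base))
            error_base <- c(A = "C", C = "A", G = "T", T = "G")[[truth_base]]
        minor <- stats::runif(depth) < minor_fraction
        base <- ifelse(minor, truth_base, error_base)
        phred <- sample(seq.int(mod_qual[1], mod_qual[2]), depth,
                        replace = TRUE)
    }
    data.frame(base = base, phred = phred, stringsAsFactors = FALSE)
}

# Simulate all reads over the draft. Returns a data.frame of read records
# sorted by position: qname, flag, pos (1-based), seq, qual (character).
.simulate_reads <- function(draft_ch, truth_ch, mod_pos1, depth,
                            read_length, read_error, minor_fraction,
                            mod_qual, bg_qual, frac_reverse) {
    L <- length(draft_ch)
    is_mod <- logical(L)
    is_mod[mod_pos1] <- TRUE
    n_draws <- round(depth * (L + read_length - 1L) / read_length)
    start0 <- sample.int(L + read_length - 1L, n_draws, replace = TRUE) -
        read_length  # 0-based, may be negative (clipped at the left end)
    s <- pmax(0L, start0)
    e <- pmin(L, start0 + read_length)
    keep <- (e - s) >= 50L
    s <- s[keep]; e <- e[keep]
    n <- length(s)
    rev_flag <- stats::runif(n) < frac_reverse

    seqs <- quals <- character(n)
    for (i in seq_len(n)) {
        p1 <- (s[i] + 1L):e[i]
        base <- draft_ch[p1]
        mod <- is_mod[p1]
        if (any(mod)) {
            minor <- stats::runif(sum(mod)) < minor_fraction
            base[mod][minor] <- truth_ch[p1[mod][minor]]
        }
        bg <- !mod
        if (read_error > 0 && any(bg)) {
            err <- stats::runif(sum(bg)) < read_error
            if (any(err)) {
                at <- which(bg)[err]
                shift <- sample.int(3L, length(at), replace = TRUE)
                code <- match(base[at], BASES)
                base[at] <- BASES[((code - 1L + shift) %% 4L) + 1L]
            }
        }
        q <- integer(length(p1))
        q[mod] <- sample(seq.int(mod_qual[1], mod_qual[2]), sum(mod),
                         replace = TRUE)
        q[!mod] <- sample(seq.int(bg_qual[1], bg_qual[2]), sum(!mod),
                          replace = TRUE)
        seqs[i] <- paste(base, collapse = "")
        quals[i] <- intToUtf8(q + 33L)
    }
    rec <- data.frame(qname = sprintf("read%05d", seq_len(n)),
                      flag = ifelse(rev_flag, 16L, 0L), pos = s + 1L,
                      seq = seqs, qual = quals, stringsAsFactors = FALSE)
    rec[order(rec$pos), , drop = FALSE]
}

.write_read_sam <- function(reads, contig, L, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", contig, L)), con)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       reads$qname, reads$flag, contig, reads$pos,
                       nchar(reads$seq), reads$seq, reads$qual), con)
    invisible(path)
}

# FASTQ stores the read as sequenced: reverse-strand reads are written as
# the reverse complement with reversed qualities.
.write_read_fastq <- function(reads, path) {
    seq <- reads$seq
    qual <- reads$qual
    rev <- reads$flag == 16L
    if (any(rev)) {
        seq[rev] <- vapply(seq[rev], .revcomp, character(1),
                           USE.NAMES = FALSE)
        qual[rev] <- vapply(strsplit(qual[rev], ""),
                            function(x) paste(rev(x), collapse = ""),
                            character(1), USE.NAMES = FALSE)
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", reads$qname, "\n", seq, "\n+\n", qual), con)
    invisible(path)
}

.write_hom_sam <- function(id, seq, contig, L, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", contig, L)), con)
    writeLines(sprintf("%s\t0\t%s\t1\t60\t%dM\t*\t0\t0\t%s\t*",
                       id, contig, nchar(seq), seq), con)
    invisible(path)
}
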