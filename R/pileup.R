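#' Per-locus pileup of reads and homologs over a draft contig
#'
#' A `PileupMatrix` is a dense per-position summary of everything aligned to
#' one draft contig: A/C/G/T allele counts from reads, A/C/G/T allele counts
#' from homolog genomes, and the summed basecall quality of the read bases.
#' It is the summary-statistics table from which candidate modified loci are
#' called: a modification perturbs the nanopore signal, so the basecaller
#' emits *inconsistent* alleles with *depressed* quality at the same locus
#' in read after read, while the homologs stay unanimous.
#'
#' Only aligned (`M`/`=`/`X`) bases contribute; insertions and deletions are
#' ignored, as are soft/hard-clipped bases and bases called `N`. Secondary,
#' supplementary and unmapped records are excluded. Records without base
#' qualities are skipped with a warning.
#'
#' @param draft draft genome (named character, `DNAStringSet`, or FASTA
#'   path).
#' @param sam path to SAM/BAM of reads aligned against the draft.
#' @param contig contig to pile up (default: the first draft record).
#' @param min_mapq minimum mapping quality (default 0 — no filter).
#' @return object of class `PileupMatrix`: list with `contig_id`,
#'   `draft_seq`, `read_counts` and `hom_counts` (4 x L integer matrices,
#'   rows A,C,G,T), `qual_sum`, `perr_sum` (summed error probabilities, for
#'   probability-space averaging) and `n_homolog_tracks`.
#' @seealso [pileup_add_homologs()], [allele_discordancy()],
#'   [find_candidates()]
#' @importFrom GenomicAlignments cigar seqnames start
#' @importFrom S4Vectors mcols
#' @export
pileup_from_read_alignments <- function(draft, sam, contig = NULL,
                                        min_mapq = 0L) {
    draft <- .as_seqs(draft)
    if (is.null(contig)) contig <- names(draft)[1]
    stopifnot(contig %in% names(draft))
    L <- nchar(draft[[contig]])

    aln <- .read_alignments(sam)
    used <- unique(as.character(GenomicAlignments::seqnames(aln)))
    offend <- setdiff(used, names(draft))
    if (length(offend))
        stop("SAM reference name(s) absent from draft: ",
             paste(offend, collapse = ", "))
    aln <- aln[as.character(GenomicAlignments::seqnames(aln)) == contig]

    mq <- S4Vectors::mcols(aln)$mapq
    aln <- aln[is.na(mq) | mq >= min_mapq]

    qual <- as.character(S4Vectors::mcols(aln)$qual)
    # '*' qualities survive BAM round-trip as 0xff bytes rendered " "
    noq <- !nzchar(gsub(" ", "", qual, fixed = TRUE)) & nzchar(qual)
    if (any(noq)) {
        warning(sum(noq), " read record(s) without base qualities skipped")
        aln <- aln[!noq]
    }

    acc <- .accumulate_alignments(aln, L, with_qual = TRUE)
    structure(list(contig_id = contig, draft_seq = draft[[contig]],
                   read_counts = acc$counts,
                   hom_counts = matrix(0L, 4, L, dimnames = list(BASES, NULL)),
                   qual_sum = acc$qual_sum, perr_sum = acc$perr_sum,
                   n_homolog_tracks = 0L),
              class = "PileupMatrix")
}

# Project aligned bases (and optionally qualities) of a GAlignments into
# reference space and accumulate per-position allele counts.
#' @importFrom Biostrings BStringSet
#' @importFrom GenomicAlignments sequenceLayer
.accumulate_alignments <- function(aln, L, with_qual = FALSE,
                                   dedupe = FALSE) {
    counts <- matrix(0L, 4, L, dimnames = list(BASES, NULL))
    qual_sum <- numeric(L)
    perr_sum <- numeric(L)
    if (length(aln) == 0L)
        return(list(counts = counts, qual_sum = qual_sum, perr_sum = perr_sum))

    lseq <- GenomicAlignments::sequenceLayer(
        S4Vectors::mcols(aln)$seq, GenomicAlignments::cigar(aln))
    w <- GenomicAlignments::width(aln)
    pos <- sequence(w, from = GenomicAlignments::start(aln))
    base <- unlist(strsplit(toupper(as.character(lseq)), "", fixed = TRUE),
                   use.names = FALSE)
    if (with_qual) {
        lq <- GenomicAlignments::sequenceLayer(
            Biostrings::BStringSet(as.character(S4Vectors::mcols(aln)$qual)),
            GenomicAlignments::cigar(aln), D.letter = "!", N.letter = "!")
        qchr <- unlist(strsplit(as.character(lq), "", fixed = TRUE),
                       use.names = FALSE)
        phred <- vapply(qchr, utf8ToInt, integer(1), USE.NAMES = FALSE) - 33L
    }
    if (dedupe) {
        keep0 <- !duplicated(pos)
        pos <- pos[keep0]; base <- base[keep0]
    }
    inside <- pos >= 1L & pos <= L
    code <- match(base, BASES)
    keep <- inside & !is.na(code)
    pos <- pos[keep]; code <- code[keep]
    idx <- (pos - 1L) * 4L + code
    counts[] <- tabulate(idx, nbins = 4L * L)
    if (with_qual) {
        q <- phred[keep]
        qs <- rowsum(q, pos)
        ps <- rowsum(10^(-q / 10), pos)
        at <- as.integer(rownames(qs))
        qual_sum[at] <- qs[, 1]
        perr_sum[at] <- ps[, 1]
    }
    list(counts = counts, qual_sum = qual_sum, perr_sum = perr_sum)
}

#' Add homolog alignment evidence to a pileup
#'
#' Homolog genomes aligned against the draft contribute allele counts only
#' (a homolog base has no basecall quality). Each element of `sams` is one
#' SAM/BAM of homolog-to-draft alignments; within a file, each distinct
#' query name is treated as one homolog evidence track and contributes at
#' most one count per draft position (overlapping or duplicated alignments
#' of the same query are deduplicated). Insertion/deletion gaps contribute
#' nothing, as for reads.
#'
#' @param matrix `PileupMatrix` from [pileup_from_read_alignments()].
#' @param sams character vector of SAM/BAM paths (typically one per homolog
#'   genome).
#' @return the `PileupMatrix` with `hom_counts` incremented and
#'   `n_homolog_tracks` updated.
#' @export
pileup_add_homologs <- function(matrix, sams) {
    stopifnot(inherits(matrix, "PileupMatrix"))
    L <- nchar(matrix$draft_seq)
    for (sam in sams) {
        aln <- .read_alignments(sam, keep_supplementary = TRUE)
        used <- unique(as.character(GenomicAlignments::seqnames(aln)))
        offend <- setdiff(used, matrix$contig_id)
        if (length(offend) && !matrix$contig_id %in% used)
            stop("homolog SAM ", sam, " has no alignments to contig ",
                 matrix$contig_id)
        aln <- aln[as.character(GenomicAlignments::seqnames(aln)) ==
                       matrix$contig_id]
        for (qn in unique(S4Vectors::mcols(aln)$qname)) {
            acc <- .accumulate_alignments(
                aln[S4Vectors::mcols(aln)$qname == qn], L, dedupe = TRUE)
            matrix$hom_counts <- matrix$hom_counts + acc$counts
            matrix$n_homolog_tracks <- matrix$n_homolog_tracks + 1L
        }
    }
    matrix
}

#' Allele discordancy of a pileup column
#'
#' The discordancy of a locus is the frequency of alternative (non-major)
#' alleles: `1 - max(counts) / sum(counts)`. A unanimous pileup has
#' discordancy 0; ties on the major allele do not change the value.
#'
#' @param counts either a length-4 vector of A,C,G,T counts or a 4 x n
#'   matrix of pileup columns.
#' @return numeric discordancy in `[0, 1]`; `NA` at zero depth.
#' @examples
#' allele_discordancy(c(1, 19, 0, 0))  # 0.05
#' @export
allele_discordancy <- function(counts) {
    # (tot - max) / tot rather than 1 - max/tot: with integer counts the
    # former is exact, so a locus at exactly 1/20 compares cleanly to 0.05
    if (is.matrix(counts)) {
        tot <- colSums(counts)
        out <- (tot - apply(counts, 2, max)) / tot
        out[tot == 0] <- NA_real_
        return(out)
    }
    tot <- sum(counts)
    if (tot == 0) return(NA_real_)
    (tot - max(counts)) / tot
}

#' Mean basecall quality per locus
#'
#' @param matrix `PileupMatrix`.
#' @param space `"phred"` (arithmetic mean of Q scores, the default) or
#'   `"probability"` (mean error probability converted back to Phred).
#' @return numeric vector over positions; `NaN` at zero read depth.
#' @export
mean_quality <- function(matrix, space = c("phred", "probability")) {
    space <- match.arg(space)
    depth <- colSums(matrix$read_counts)
    if (space == "phred") matrix$qual_sum / depth
    else -10 * log10(matrix$perr_sum / depth)
}

#' @export
print.PileupMatrix <- function(x, ...) {
    depth <- colSums(x$read_counts)
    cat(sprintf(
        "PileupMatrix %s: %d bp, mean read depth %.1f, %d homolog track(s)\n",
        x$contig_id, nchar(x$draft_seq), mean(depth), x$n_homolog_tracks))
    invisible(x)
}

#' @export
as.data.frame.PileupMatrix <- function(x, ...) {
    depth <- colSums(x$read_counts)
    data.frame(
        position = seq_len(nchar(x$draft_seq)) - 1L,
        draft_allele = strsplit(x$draft_seq, "")[[1]],
        read_A = x$read_counts["A", ], read_C = x$read_counts["C", ],
        read_G = x$read_counts["G", ], read_T = x$read_counts["T", ],
        hom_A = x$hom_counts["A", ], hom_C = x$hom_counts["C", ],
        hom_G = x$hom_counts["G", ], hom_T = x$hom_counts["T", ],
        read_depth = depth, homolog_depth = colSums(x$hom_counts),
        mean_quality = x$qual_sum / depth,
        stringsAsFactors = FALSE)
}

#' Align reads to the draft with minimap2
#'
#' Thin convenience wrapper: maps a FASTQ of nanopore reads against the
#' draft with minimap2 (default preset `map-ont`) and coordinate-sorts the
#' result. All core computation accepts pre-aligned SAM directly, so this
#' step is optional.
#'
#' @param reads FASTQ path.
#' @param draft FASTA path (or sequences, written to a temp file).
#' @param preset minimap2 preset (default `"map-ont"`).
#' @param out output SAM path (default: temp file).
#' @return path to the sorted SAM.
#' @export
align_reads <- function(reads, draft, preset = "map-ont",
                        out = tempfile(fileext = ".sam")) {
    .check_tool("minimap2",
                "Install minimap2 or supply a pre-aligned SAM via `sam=`.")
    dfa <- if (is.character(draft) && length(draft) == 1L && file.exists(draft))
        draft else .write_fasta(draft, tempfile(fileext = ".fa"))
    raw <- .run_minimap2(dfa, reads, preset = preset, sam = TRUE)
    if (nzchar(Sys.which("samtools"))) {
        status <- system2("samtools", c("sort", "-O", "sam", "-o",
                                        shQuote(out), shQuote(raw)))
        if (status != 0L) stop("samtools sort failed")
    } else {
        file.copy(raw, out, overwrite = TRUE)
    }
    out
}
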