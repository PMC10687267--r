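#' Phred-scaled assembly quality score
#'
#' `Q = -10 * log10(errors / aligned_length)`, capped at `cap` (default 60,
#' the conventional ceiling); zero errors report the cap directly. One
#' mismatch over 10,000 aligned bases is exactly Q40.
#'
#' @param errors total error count (mismatches + indel bases).
#' @param aligned_length aligned bases.
#' @param cap maximum reported Q (default 60).
#' @return numeric Q score; `NA` when `aligned_length` is 0.
#' @export
q_score <- function(errors, aligned_length, cap = 60) {
    if (aligned_length <= 0) return(NA_real_)
    if (errors <= 0) return(cap)
    min(cap, -10 * log10(errors / aligned_length))
}

#' Evaluate assembly accuracy against a reference
#'
#' Aligns the assembly to the reference with minimap2 (whole-genome
#' chained alignment, primary and supplementary segments kept, secondary
#' dropped) and counts mismatches, inserted and deleted bases over the
#' aligned blocks from the exact (`=`/`X`) CIGARs. Indels are counted
#' per base by default; `indel_per_event = TRUE` counts each indel run
#' once. Unaligned assembly ends are excluded from `aligned_length`.
#'
#' @param assembly assembly sequences or FASTA path.
#' @param reference reference sequences or FASTA path.
#' @param cap Q-score cap (default 60).
#' @param indel_per_event count indel events instead of indel bases.
#' @param preset minimap2 preset (default `"asm5"`).
#' @return object of class `QualityReport`: list with `aligned_length`,
#'   `mismatches`, `insertions`, `deletions`, `errors`, `q_score` and
#'   `identity`.
#' @importFrom GenomicAlignments cigarOpTable explodeCigarOps
#' @export
assembly_quality <- function(assembly, reference, cap = 60,
                             indel_per_event = FALSE, preset = "asm5") {
    afa <- if (is.character(assembly) && length(assembly) == 1L &&
               file.exists(assembly)) assembly
           else .write_fasta(assembly, tempfile(fileext = ".fa"))
    rfa <- if (is.character(reference) && length(reference) == 1L &&
               file.exists(reference)) reference
           else .write_fasta(reference, tempfile(fileext = ".fa"))
    sam <- .run_minimap2(rfa, afa, preset = preset, sam = TRUE)
    aln <- .read_alignments(sam, keep_supplementary = TRUE)
    if (length(aln) == 0L) {
        return(structure(list(aligned_length = 0L, mismatches = 0L,
                              insertions = 0L, deletions = 0L, errors = 0L,
                              q_score = NA_real_, identity = NA_real_),
                         class = "QualityReport"))
    }
    cig <- GenomicAlignments::cigar(aln)
    opw <- GenomicAlignments::cigarOpTable(cig)
    matches <- sum(opw[, "="]) + sum(opw[, "M"])
    mism <- sum(opw[, "X"])
    if (indel_per_event) {
        ops <- unlist(GenomicAlignments::explodeCigarOps(cig),
                      use.names = FALSE)
        ins <- sum(ops == "I")
        del <- sum(ops == "D")
    } else {
        ins <- sum(opw[, "I"])
        del <- sum(opw[, "D"])
    }
    aligned <- matches + mism
    errors <- mism + ins + del
    structure(list(aligned_length = aligned, mismatches = mism,
                   insertions = ins, deletions = del, errors = errors,
                   q_score = q_score(errors, aligned, cap = cap),
                   identity = if (aligned > 0) matches / aligned
                              else NA_real_),
              class = "QualityReport")
}

#' @export
print.QualityReport <- function(x, ...) {
    cat(sprintf(
        "QualityReport: Q %.2f | %d mismatch(es), %d ins, %d del over %d aligned bp (identity %.5f)\n",
        x$q_score, x$mismatches, x$insertions, x$deletions,
        x$aligned_length, x$identity))
    invisible(x)
}
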