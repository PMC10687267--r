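#' Extract sequence windows around corrected loci
#'
#' Cuts a fixed-width window centered on each corrected position; windows
#' that would overhang a contig end are dropped. Because a modification
#' system targets a motif irrespective of strand, each window is by default
#' replaced by the lexicographically smaller of itself and its reverse
#' complement, making downstream motif reports invariant to
#' reverse-complementing the genome.
#'
#' @param genome contig sequence (character, `DNAString`, or FASTA path —
#'   first record).
#' @param corrected_positions 0-based positions of corrected loci.
#' @param width odd window width in bases (default 11).
#' @param canonical canonicalize windows by strand (default `TRUE`).
#' @return character vector of windows (possibly empty).
#' @export
extract_windows <- function(genome, corrected_positions, width = 11L,
                            canonical = TRUE) {
    if (width %% 2L == 0L) stop("width must be odd")
    seq <- .as_seqs(genome)[[1]]
    L <- nchar(seq)
    half <- (width - 1L) %/% 2L
    pos1 <- as.integer(corrected_positions) + 1L
    keep <- pos1 - half >= 1L & pos1 + half <= L
    if (!any(keep)) return(character(0))
    w <- substring(seq, pos1[keep] - half, pos1[keep] + half)
    if (canonical) {
        rc <- vapply(w, .revcomp, character(1), USE.NAMES = FALSE)
        w <- pmin(w, rc)
    }
    unname(w)
}

.IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Build a motif report from corrected-locus windows
#'
#' Summarizes the sequence context of corrected loci as a position
#' frequency matrix (PFM), a per-column IUPAC consensus, and a ranked list
#' of k-mers overlapping the window center. The consensus rule per column:
#' the single base if its frequency is at least 0.75; the two-base IUPAC
#' code if the top two bases together reach 0.9; otherwise `N`. The center
#' k-mer scan counts, for each window, every k-mer whose span covers the
#' center position (strand-canonicalized), so a planted motif is recovered
#' regardless of where the modified base sits inside it.
#'
#' @param windows character vector of equal-width windows from
#'   [extract_windows()].
#' @param k k-mer length of the center scan (default 5, pentanucleotide).
#' @return object of class `MotifReport`: list with `window_width`,
#'   `n_windows`, `position_frequency_matrix` (4 x width counts),
#'   `consensus`, and `top_kmers` (data.frame `kmer`, `count`, `fraction`
#'   of windows containing the k-mer over the center, ranked by count then
#'   k-mer).
#' @export
build_motif <- function(windows, k = 5L) {
    if (length(windows) == 0L) stop("no windows: nothing to summarise")
    width <- unique(nchar(windows))
    if (length(width) != 1L) stop("windows must share one width")
    if (k > width) stop("k exceeds window width")

    pfm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
    m <- matrix(0L, 4, width, dimnames = list(BASES, NULL))
    common <- intersect(rownames(pfm), BASES)
    m[common, ] <- pfm[common, , drop = FALSE]

    n <- length(windows)
    consensus <- vapply(seq_len(width), function(j) {
        fr <- sort(m[, j] / n, decreasing = TRUE)
        if (fr[1] >= 0.75) return(names(fr)[1])
        if (fr[1] + fr[2] >= 0.9) {
            pair <- paste(sort(names(fr)[1:2]), collapse = "")
            return(.IUPAC2[[pair]])
        }
        "N"
    }, character(1))
    consensus <- paste(consensus, collapse = "")

    center <- (width + 1L) %/% 2L
    starts <- max(1L, center - k + 1L):min(center, width - k + 1L)
    per_window <- lapply(windows, function(w) {
        km <- substring(w, starts, starts + k - 1L)
        rc <- vapply(km, .revcomp, character(1), USE.NAMES = FALSE)
        unique(pmin(km, rc))
    })
    counts <- table(unlist(per_window, use.names = FALSE))
    tk <- data.frame(kmer = names(counts), count = as.integer(counts),
                     fraction = as.integer(counts) / n,
                     stringsAsFactors = FALSE)
    tk <- tk[order(-tk$count, tk$kmer), , drop = FALSE]
    rownames(tk) <- NULL

    structure(list(window_width = width, n_windows = n,
                   position_frequency_matrix = m, consensus = consensus,
                   top_kmers = tk),
              class = "MotifReport")
}

#' @export
print.MotifReport <- function(x, ...) {
    cat(sprintf("MotifReport: %d window(s) of width %d, consensus %s\n",
                x$n_windows, x$window_width, x$consensus))
    cat("Top k-mers over the center:\n")
    print(utils::head(x$top_kmers, 5), row.names = FALSE)
    invisible(x)
}

#' Motif report for a polished genome
#'
#' Convenience wrapper: reads corrected positions (from a [polish()]
#' result, a corrections data.frame, or a BED file) and builds the
#' [build_motif()] report against the genome. Optionally writes the report
#' as JSON plus a plain-text PFM table.
#'
#' @param genome contig sequence or FASTA path.
#' @param corrections a data.frame with a `position` column (0-based), a
#'   BED path, or a numeric vector of 0-based positions.
#' @param width,k,canonical see [extract_windows()] and [build_motif()].
#' @param out optional JSON output path; the PFM is written next to it
#'   with extension `.pfm.tsv`.
#' @return `MotifReport`.
#' @export
motif_report <- function(genome, corrections, width = 11L, k = 5L,
                         canonical = TRUE, out = NULL) {
    pos <- if (is.numeric(corrections)) as.integer(corrections)
    else if (is.data.frame(corrections)) as.integer(corrections$position)
    else if (is.character(corrections) && file.exists(corrections)) {
        bed <- utils::read.table(corrections, sep = "\t",
                                 stringsAsFactors = FALSE)
        as.integer(bed[[2]])
    } else stop("cannot interpret `corrections`")
    win <- extract_windows(genome, pos, width = width, canonical = canonical)
    if (length(win) == 0L) {
        rep <- structure(list(window_width = width, n_windows = 0L,
                              position_frequency_matrix =
                                  matrix(0L, 4, width,
                                         dimnames = list(BASES, NULL)),
                              consensus = strrep("N", width),
                              top_kmers = data.frame(kmer = character(),
                                                     count = integer(),
                                                     fraction = numeric())),
                         class = "MotifReport")
    } else {
        rep <- build_motif(win, k = k)
    }
    if (!is.null(out)) {
        jsonlite::write_json(
            list(window_width = rep$window_width, n_windows = rep$n_windows,
                 consensus = rep$consensus, top_kmers = rep$top_kmers,
                 position_frequency_matrix =
                     as.data.frame(t(rep$position_frequency_matrix))),
            out, auto_unbox = TRUE, pretty = TRUE)
        utils::write.table(rep$position_frequency_matrix,
                           sub("\\.json$", ".pfm.tsv", out), sep = "\t",
                           quote = FALSE, col.names = FALSE)
    }
    rep
}
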