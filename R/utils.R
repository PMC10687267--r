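#' @useDynLib modpolisher, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString reverseComplement
.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Coerce a genome argument (character vector, file path, DNAString(Set)) to a
# plain named character vector of record sequences.
#' @importFrom Biostrings readDNAStringSet DNAStringSet
.as_seqs <- function(x) {
    if (is(x, "DNAStringSet")) return(structure(as.character(x), names = names(x)))
    if (is(x, "DNAString")) return(c(seq = as.character(x)))
    if (is.character(x) && length(x) == 1L && file.exists(x) &&
        grepl("\\.(fa|fasta|fna|ffn)(\\.gz)?$", x, ignore.case = TRUE)) {
        ss <- Biostrings::readDNAStringSet(x)
        nm <- sub("\\s.*$", "", names(ss))
        return(structure(toupper(as.character(ss)), names = nm))
    }
    if (is.character(x)) {
        out <- toupper(x)
        if (is.null(names(out)))
            names(out) <- if (length(out) == 1L) "seq" else paste0("seq", seq_along(out))
        return(out)
    }
    stop("cannot interpret sequence input of class ", class(x)[1])
}

.check_tool <- function(tool, hint) {
    path <- Sys.which(tool)
    if (!nzchar(path))
        stop(tool, " was not found on PATH. ", hint, call. = FALSE)
    invisible(path)
}

.write_fasta <- function(seqs, path) {
    seqs <- .as_seqs(seqs)
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
        writeLines(paste0(">", names(seqs)[i]), con)
        s <- seqs[[i]]
        starts <- seq(1L, nchar(s), by = 80L)
        writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
    }
    invisible(path)
}

# Run minimap2 and return the path to its output (PAF or SAM).
.run_minimap2 <- function(ref_fa, query_fa, preset = "asm5", sam = FALSE,
                          extra = character()) {
    .check_tool("minimap2",
                "Install minimap2 or supply pre-aligned SAM instead.")
    out <- tempfile(fileext = if (sam) ".sam" else ".paf")
    args <- c("-x", preset, "--eqx", if (sam) "-a" else "-c", extra,
              shQuote(ref_fa), shQuote(query_fa))
    status <- system2("minimap2", args, stdout = out, stderr = FALSE)
    if (status != 0L) stop("minimap2 exited with status ", status)
    out
}

# Read a SAM or BAM file into a GAlignments object with seq/qual/mapq/flag,
# excluding secondary, supplementary and unmapped records unless asked
# otherwise. Malformed-CIGAR records in SAM text are dropped with a warning
# (samtools would otherwise refuse the whole file).
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag BamFile
#' @importFrom GenomicAlignments readGAlignments
.read_alignments <- function(path, keep_supplementary = FALSE) {
    stopifnot(file.exists(path))
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        lines <- readLines(path)
        hdr <- grepl("^@", lines)
        rec <- !hdr
        fields <- strsplit(lines[rec], "\t", fixed = TRUE)
        ok <- vapply(fields, function(f) {
            length(f) >= 11L &&
                grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", f[6])
        }, logical(1))
        if (any(!ok)) {
            warning(sum(!ok), " SAM record(s) with malformed CIGAR skipped")
            tmp <- tempfile(fileext = ".sam")
            writeLines(c(lines[hdr], lines[rec][ok]), tmp)
            path <- tmp
        }
        bam <- suppressMessages(Rsamtools::asBam(
            path, tempfile(), overwrite = TRUE, indexDestination = FALSE))
    } else {
        bam <- path
    }
    flag <- Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = if (keep_supplementary) NA else FALSE)
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "seq", "qual", "mapq", "flag"), flag = flag)
    GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam), param = param)
}

.log_msg <- function(...) {
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
}
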