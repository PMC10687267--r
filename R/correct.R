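#' Identify potentially modified loci
#'
#' A locus is a candidate modified site when its read pileup is both
#' discordant and of low basecall quality: allele discordancy strictly
#' greater than `discordancy_min` *and* mean quality strictly below
#' `quality_max` (both inequalities strict, so a locus at exactly 5%
#' discordancy or exactly Q15 is not a candidate). Loci below the read or
#' homolog depth floors are skipped — conservation estimated from one or
#' two homologs is not evidence.
#'
#' @param matrix `PileupMatrix` with read and homolog fields populated.
#' @param discordancy_min discordancy threshold, strict (default 0.05).
#' @param quality_max mean-quality threshold in Phred units, strict
#'   (default 15).
#' @param min_read_depth minimum read depth at a candidate (default 5).
#' @param min_homolog_depth minimum homolog depth at a candidate
#'   (default 3).
#' @param quality_space how read quality is averaged (see
#'   [mean_quality()]).
#' @return data.frame of candidate loci: `position` (0-based),
#'   `draft_allele`, `discordancy`, `mean_quality`, `read_depth`,
#'   `homolog_depth`, `homolog_consensus_allele` (`NA` on a tie),
#'   `homolog_conservation`, `matched_motif` (filled by
#'   [apply_corrections()]). The number of loci rejected only by the depth
#'   floors is recorded in attribute `n_skipped_depth`.
#' @export
find_candidates <- function(matrix, discordancy_min = 0.05, quality_max = 15,
                            min_read_depth = 5L, min_homolog_depth = 3L,
                            quality_space = "phred") {
    stopifnot(inherits(matrix, "PileupMatrix"))
    depth <- colSums(matrix$read_counts)
    hdepth <- colSums(matrix$hom_counts)
    disc <- allele_discordancy(matrix$read_counts)
    mq <- mean_quality(matrix, space = quality_space)

    signal <- !is.na(disc) & disc > discordancy_min &
        is.finite(mq) & mq < quality_max
    deep <- depth >= min_read_depth & hdepth >= min_homolog_depth
    is_cand <- signal & deep
    pos <- which(is_cand)
    if (length(pos) == 0L) {
        out <- data.frame(position = integer(), draft_allele = character(),
                          discordancy = numeric(), mean_quality = numeric(),
                          read_depth = integer(), homolog_depth = integer(),
                          homolog_consensus_allele = character(),
                          homolog_conservation = numeric(),
                          matched_motif = logical(),
                          stringsAsFactors = FALSE)
        attr(out, "n_skipped_depth") <- sum(signal & !deep)
        return(out)
    }

    cons <- homolog_conservation(matrix$hom_counts[, pos, drop = FALSE])
    out <- data.frame(
        position = pos - 1L,
        draft_allele = substring(matrix$draft_seq, pos, pos),
        discordancy = disc[pos],
        mean_quality = mq[pos],
        read_depth = depth[pos],
        homolog_depth = hdepth[pos],
        homolog_consensus_allele = cons$consensus,
        homolog_conservation = cons$conservation,
        matched_motif = NA,
        stringsAsFactors = FALSE)
    attr(out, "n_skipped_depth") <- sum(signal & !deep)
    out
}

#' Homolog consensus allele and conservation
#'
#' The consensus is the allele with the maximal homolog count; its
#' conservation is `max(counts) / sum(counts)` — the fraction of aligned
#' homologs agreeing with it. A tie for the maximum leaves the consensus
#' undefined (`NA`), with the conservation of the tied maximum still
#' reported.
#'
#' @param counts length-4 A,C,G,T count vector, or a 4 x n matrix of
#'   columns.
#' @return for a vector, `list(consensus =, conservation =)`; for a matrix,
#'   a data.frame with one row per column. Zero depth yields `NA`s.
#' @examples
#' homolog_conservation(c(0, 19, 0, 1))  # consensus "C", conservation 0.95
#' @export
homolog_conservation <- function(counts) {
    vec <- !is.matrix(counts)
    m <- if (vec) matrix(counts, 4) else counts
    tot <- colSums(m)
    mx <- apply(m, 2, max)
    consensus <- vapply(seq_len(ncol(m)), function(i) {
        if (tot[i] == 0) return(NA_character_)
        w <- which(m[, i] == mx[i])
        if (length(w) != 1L) NA_character_ else BASES[w]
    }, character(1))
    conservation <- ifelse(tot == 0, NA_real_, mx / tot)
    if (vec) list(consensus = consensus[1], conservation = conservation[1])
    else data.frame(consensus = consensus, conservation = conservation,
                    stringsAsFactors = FALSE)
}

# Logical mask over the contig: TRUE where the position lies inside an
# occurrence of the motif on either strand. W (A/T) and S (C/G) are
# expanded; other ambiguity codes are rejected.
#' @importFrom Biostrings matchPattern
#' @importFrom IRanges IRanges coverage
.motif_cover <- function(seq, motif) {
    motif <- toupper(motif)
    bad <- setdiff(strsplit(motif, "")[[1]], c(BASES, "W", "S"))
    if (length(bad))
        stop("unsupported motif character(s): ", paste(bad, collapse = ","),
             " (ACGT plus IUPAC W/S are supported)")
    subject <- Biostrings::DNAString(seq)
    hits <- c(
        as(Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                    fixed = FALSE), "IRanges"),
        as(Biostrings::matchPattern(
            Biostrings::reverseComplement(Biostrings::DNAString(motif)),
            subject, fixed = FALSE), "IRanges"))
    cov <- logical(nchar(seq))
    if (length(hits))
        for (i in seq_along(hits)) {
            s <- IRanges::start(hits)[i]; e <- IRanges::end(hits)[i]
            cov[s:e] <- TRUE
        }
    cov
}

#' Apply conservation-gated corrections
#'
#' For each candidate locus the homolog consensus allele is the proposed
#' replacement. The correction is applied only when every gate passes:
#' the consensus is defined (no tie), differs from the draft allele, is
#' observed among the read alleles at the locus (the homolog-concordant
#' *alternative* allele must exist in the pileup; relax with
#' `allow_unseen_allele`), and the homolog conservation reaches the
#' required level — 100% by default, relaxed to `conservation_motif`
#' (default 80%) when the locus lies inside an occurrence of a
#' user-supplied modified motif on either strand. Specificity comes first:
#' anything short of full conservation is treated as possible strain
#' variation and left alone.
#'
#' Corrections are single-base substitutions, so coordinates never shift.
#'
#' @param matrix `PileupMatrix`.
#' @param candidates data.frame from [find_candidates()].
#' @param motif optional known modified motif (e.g. `"CCGAC"`; IUPAC W/S
#'   supported).
#' @param conservation_default conservation required outside the motif
#'   (default 1.0, compared exactly — integer counts make 100% exact).
#' @param conservation_motif conservation required inside a motif
#'   occurrence (default 0.8, compared with `>=`).
#' @param allow_unseen_allele if `TRUE`, correct even when no read carries
#'   the consensus allele.
#' @return list with `sequence` (polished contig, character) and `report`
#'   (a `PolishReport`: per-contig counters, the parameter snapshot, the
#'   corrections table and the skipped-candidates table with reasons).
#' @export
apply_corrections <- function(matrix, candidates, motif = NULL,
                              conservation_default = 1.0,
                              conservation_motif = 0.8,
                              allow_unseen_allele = FALSE) {
    stopifnot(inherits(matrix, "PileupMatrix"))
    seq <- matrix$draft_seq
    n <- nrow(candidates)
    covered <- if (!is.null(motif) && n > 0)
        .motif_cover(seq, motif)[candidates$position + 1L] else rep(FALSE, n)
    candidates$matched_motif <- covered

    corrections <- data.frame(
        position = integer(), old_allele = character(),
        new_allele = character(), homolog_conservation = numeric(),
        read_support_of_new_allele = numeric(), mode = character(),
        stringsAsFactors = FALSE)
    skipped <- data.frame(position = integer(), reason = character(),
                          stringsAsFactors = FALSE)

    chars <- strsplit(seq, "")[[1]]
    for (i in seq_len(n)) {
        p1 <- candidates$position[i] + 1L
        cons <- candidates$homolog_consensus_allele[i]
        f <- candidates$homolog_conservation[i]
        mode <- if (covered[i]) "motif" else "default"
        required <- if (covered[i]) conservation_motif else conservation_default
        reason <- NULL
        if (is.na(cons)) {
            reason <- "consensus_tie"
        } else if (f < required) {
            reason <- "low_conservation"
        } else if (cons == chars[p1]) {
            reason <- "consensus_equals_draft"
        } else if (!allow_unseen_allele &&
                   matrix$read_counts[cons, p1] == 0L) {
            reason <- "allele_not_in_reads"
        }
        if (is.null(reason)) {
            support <- matrix$read_counts[cons, p1] /
                sum(matrix$read_counts[, p1])
            corrections <- rbind(corrections, data.frame(
                position = candidates$position[i], old_allele = chars[p1],
                new_allele = cons, homolog_conservation = f,
                read_support_of_new_allele = support, mode = mode,
                stringsAsFactors = FALSE))
            chars[p1] <- cons
        } else {
            skipped <- rbind(skipped, data.frame(
                position = candidates$position[i], reason = reason,
                stringsAsFactors = FALSE))
        }
    }

    report <- structure(list(
        contig_id = matrix$contig_id,
        n_candidates = n,
        n_corrections = nrow(corrections),
        n_skipped_conservation =
            sum(skipped$reason %in% c("low_conservation", "consensus_tie")),
        n_skipped_depth = attr(candidates, "n_skipped_depth") %||% NA_integer_,
        parameters = list(motif = motif,
                          conservation_default = conservation_default,
                          conservation_motif = conservation_motif,
                          allow_unseen_allele = allow_unseen_allele),
        corrections = corrections, skipped = skipped),
        class = "PolishReport")
    list(sequence = paste(chars, collapse = ""), report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.PolishReport <- function(x, ...) {
    cat(sprintf(
        "PolishReport %s: %d candidate(s), %d correction(s), %d skipped by conservation\n",
        x$contig_id, x$n_candidates, x$n_corrections,
        x$n_skipped_conservation))
    invisible(x)
}

#' Polish a draft genome against reads and homologs
#'
#' End-to-end composition: build the read pileup per contig, add homolog
#' evidence, call candidate modified loci, and apply conservation-gated
#' corrections. Deterministic for fixed inputs. Refuses to run without
#' homolog alignments — conservation is undefined without homologs.
#'
#' @param draft draft genome (named character, `DNAStringSet`, or FASTA
#'   path).
#' @param read_sam SAM/BAM of reads aligned to the draft.
#' @param homolog_sams character vector of homolog-to-draft SAM/BAM paths.
#' @param out_dir optional output directory; when given, writes
#'   `polished.fasta`, `corrections.tsv`, `corrections.bed` (0-based
#'   half-open single-base intervals) and `report.json`.
#' @param motif optional known modified motif (see [apply_corrections()]).
#' @inheritParams find_candidates
#' @inheritParams apply_corrections
#' @return list with `polished` (named character vector of contig
#'   sequences), `reports` (list of `PolishReport` per contig) and
#'   `corrections` (combined data.frame with a `contig` column).
#' @export
polish <- function(draft, read_sam, homolog_sams, out_dir = NULL,
                   motif = NULL, discordancy_min = 0.05, quality_max = 15,
                   min_read_depth = 5L, min_homolog_depth = 3L,
                   conservation_default = 1.0, conservation_motif = 0.8,
                   allow_unseen_allele = FALSE, min_mapq = 0L,
                   quality_space = "phred") {
    if (length(homolog_sams) == 0L)
        stop("no homolog alignments supplied; conservation is undefined ",
             "without homologs. Provide at least one homolog-to-draft SAM ",
             "or run homolog selection first.")
    draft <- .as_seqs(draft)
    polished <- draft
    reports <- list()
    all_corr <- NULL
    total_tracks <- 0L
    for (ctg in names(draft)) {
        pm <- pileup_from_read_alignments(draft, read_sam, contig = ctg,
                                          min_mapq = min_mapq)
        pm <- pileup_add_homologs(pm, homolog_sams)
        total_tracks <- total_tracks + pm$n_homolog_tracks
        cand <- find_candidates(pm, discordancy_min = discordancy_min,
                                quality_max = quality_max,
                                min_read_depth = min_read_depth,
                                min_homolog_depth = min_homolog_depth,
                                quality_space = quality_space)
        res <- apply_corrections(pm, cand, motif = motif,
                                 conservation_default = conservation_default,
                                 conservation_motif = conservation_motif,
                                 allow_unseen_allele = allow_unseen_allele)
        polished[[ctg]] <- res$sequence
        reports[[ctg]] <- res$report
        if (nrow(res$report$corrections))
            all_corr <- rbind(all_corr,
                              cbind(contig = ctg, res$report$corrections,
                                    stringsAsFactors = FALSE))
    }
    if (total_tracks == 0L)
        stop("homolog SAM(s) contained no usable alignments; conservation ",
             "is undefined without homologs")
    if (is.null(all_corr))
        all_corr <- data.frame(contig = character(), position = integer(),
                               old_allele = character(),
                               new_allele = character(),
                               homolog_conservation = numeric(),
                               read_support_of_new_allele = numeric(),
                               mode = character(), stringsAsFactors = FALSE)
    out <- list(polished = polished, reports = reports,
                corrections = all_corr)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        .write_fasta(polished, file.path(out_dir, "polished.fasta"))
        utils::write.table(all_corr, file.path(out_dir, "corrections.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        bed <- data.frame(chrom = all_corr$contig, start = all_corr$position,
                          end = all_corr$position + 1L,
                          name = paste0(all_corr$old_allele, ">",
                                        all_corr$new_allele))
        utils::write.table(bed, file.path(out_dir, "corrections.bed"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        jsonlite::write_json(
            lapply(reports, function(r) r[c("contig_id", "n_candidates",
                                            "n_corrections",
                                            "n_skipped_conservation",
                                            "n_skipped_depth",
                                            "parameters")]),
            file.path(out_dir, "report.json"), auto_unbox = TRUE,
            null = "null", pretty = TRUE)
    }
    out
}
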