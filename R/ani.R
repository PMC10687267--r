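#' Fragment-based average nucleotide and structural identity
#'
#' Re-estimates the similarity of a candidate homolog to the draft at higher
#' resolution than a MinHash sketch. The query genome is chopped into
#' consecutive non-overlapping fragments of `fragment_length` bases (a
#' terminal remainder shorter than half a fragment is dropped; a longer one
#' is kept as a final short fragment, and fragments never span FASTA
#' records). Each fragment is aligned to the reference with minimap2. A
#' fragment counts as *aligned* when the exactly matching bases of its best
#' alignment cover at least `aligned_threshold` of the fragment length; the
#' nucleotide identity entering ANI is matches over the alignment's column
#' count, so a few soft-clipped terminal bases are not charged as
#' mismatches.
#'
#' ANI (average nucleotide identity) is the mean identity over aligned
#' fragments, in percent; ASI (average structural identity) is the
#' percentage of fragments that aligned at all, so structural variation
#' (insertions, deletions, transferred genes) between two otherwise close
#' genomes depresses ASI while leaving ANI high.
#'
#' @param query genome chopped into fragments (character, `DNAStringSet`, or
#'   FASTA path) — conventionally the candidate homolog.
#' @param reference genome aligned against — conventionally the draft.
#' @param fragment_length fragment size in bases (default 3000, minimum 100).
#' @param aligned_threshold identity above which a fragment counts as
#'   aligned (default 0.80).
#' @param preset minimap2 preset used for the fragment mapping.
#' @return named numeric vector `c(ani =, asi =)`, both in percent; `ani` is
#'   `NA` when no fragment aligns.
#' @export
fragment_ani <- function(query, reference, fragment_length = 3000L,
                         aligned_threshold = 0.80, preset = "asm5") {
    if (fragment_length < 100L) stop("fragment_length must be >= 100")
    qseqs <- .as_seqs(query)
    frags <- character(0)
    for (s in qseqs) {
        L <- nchar(s)
        if (L < fragment_length / 2) next
        starts <- seq(1L, L, by = fragment_length)
        ends <- pmin(starts + fragment_length - 1L, L)
        keep <- (ends - starts + 1L) >= fragment_length / 2
        frags <- c(frags, substring(s, starts[keep], ends[keep]))
    }
    if (length(frags) == 0L)
        stop("query too short: no fragments of at least fragment_length/2")
    names(frags) <- paste0("frag", seq_along(frags))

    qfa <- .write_fasta(frags, tempfile(fileext = ".fa"))
    rfa <- .write_fasta(.as_seqs(reference), tempfile(fileext = ".fa"))
    paf <- .run_minimap2(rfa, qfa, preset = preset)
    nmatch <- stats::setNames(numeric(length(frags)), names(frags))
    alen <- stats::setNames(rep(NA_real_, length(frags)), names(frags))
    lines <- readLines(paf)
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        nm <- as.numeric(f[10])
        if (nm > nmatch[[f[1]]]) {
            nmatch[[f[1]]] <- nm
            alen[[f[1]]] <- as.numeric(f[11])
        }
    }
    coverage_id <- nmatch / nchar(frags)
    aligned <- coverage_id >= aligned_threshold
    asi <- 100 * sum(aligned) / length(frags)
    ani <- if (any(aligned))
        100 * mean(nmatch[aligned] / alen[aligned]) else NA_real_
    c(ani = ani, asi = asi)
}

#' Filter ranked homologs by ANI and ASI, with a fallback
#'
#' Primary pass keeps records with `ani > ani_min` and `asi > asi_min`
#' (strict inequalities). If fewer than `min_retained` survive, the strict
#' filter is abandoned and *all* input records (the Mash-identity screen)
#' are returned with `fallback_used = TRUE` — with too few fully similar
#' genomes, conservation evidence is better drawn from the wider Mash set
#' than from almost none.
#'
#' @param records data.frame as produced by [rank_candidates()] with `ani`
#'   and `asi` columns filled in.
#' @param ani_min ANI retention cutoff in percent, strict (default 99).
#' @param asi_min ASI retention cutoff in percent, strict (default 90).
#' @param min_retained minimum number of genomes the strict pass must
#'   retain (default 3).
#' @return data.frame of retained records; `retained` is set and
#'   `fallback_used` flags every record when the fallback fired.
#' @export
filter_homologs <- function(records, ani_min = 99, asi_min = 90,
                            min_retained = 3L) {
    if (nrow(records) == 0L) {
        records$retained <- logical(0)
        records$fallback_used <- logical(0)
        return(records)
    }
    pass <- !is.na(records$ani) & records$ani > ani_min & records$asi > asi_min
    if (sum(pass) >= min_retained) {
        out <- records[pass, , drop = FALSE]
        out$retained <- TRUE
        out$fallback_used <- FALSE
    } else {
        out <- records
        out$retained <- TRUE
        out$fallback_used <- TRUE
    }
    rownames(out) <- NULL
    out
}

#' Select homolog genomes for polishing
#'
#' End-to-end homolog selection: sketch the draft, rank a sketch database by
#' Mash identity, re-estimate each surviving candidate with [fragment_ani()]
#' against the draft, and apply [filter_homologs()].
#'
#' @param draft draft genome (character, `DNAStringSet`, or FASTA path).
#' @param db named list of `GenomeSketch` (see [build_sketch_db()]).
#' @param genomes named list/vector mapping genome ids to their sequences or
#'   FASTA paths, used for the fragment-ANI stage.
#' @param t,mash_min passed to [rank_candidates()].
#' @param ani_min,asi_min,min_retained passed to [filter_homologs()].
#' @param fragment_length,aligned_threshold passed to [fragment_ani()].
#' @return data.frame of retained similarity records.
#' @export
select_homologs <- function(draft, db, genomes, t = 20L, mash_min = 0.95,
                            ani_min = 99, asi_min = 90, min_retained = 3L,
                            fragment_length = 3000L,
                            aligned_threshold = 0.80) {
    stopifnot(length(db) > 0L)
    proto <- db[[1]]
    dsk <- build_sketch(draft, k = proto$k, sketch_size = proto$sketch_size,
                        seed = proto$seed, genome_id = "draft")
    rec <- rank_candidates(dsk, db, t = t, min_identity = mash_min)
    for (i in seq_len(nrow(rec))) {
        g <- genomes[[rec$genome_id[i]]]
        if (is.null(g)) stop("no sequence available for candidate ",
                             rec$genome_id[i])
        aa <- fragment_ani(g, draft, fragment_length = fragment_length,
                           aligned_threshold = aligned_threshold)
        rec$ani[i] <- aa[["ani"]]
        rec$asi[i] <- aa[["asi"]]
    }
    filter_homologs(rec, ani_min = ani_min, asi_min = asi_min,
                    min_retained = min_retained)
}
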