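#' MinHash genome sketches
#'
#' A `GenomeSketch` is a bottom-s MinHash sketch of a genome: the s smallest
#' 53-bit hash values of its distinct canonical k-mers (each k-mer is read as
#' the lexicographically smaller of itself and its reverse complement, so
#' sketches are strand-symmetric). Comparing two sketches estimates the
#' Jaccard similarity of the full k-mer sets, from which a Mash-style
#' identity is derived; this is the fast first-pass screen used to pull
#' closely related genomes out of a local sketch database.
#'
#' K-mers containing non-ACGT characters are skipped. Multi-record FASTA
#' input is sketched per record (k-mers never span records) and pooled into
#' one sketch per genome.
#'
#' @param sequence genome sequence: a character vector of record sequences, a
#'   `DNAStringSet`, or a FASTA file path.
#' @param k k-mer length in bases (2..31; default 21, Mash's default).
#' @param sketch_size maximum number of retained hashes (default 1000).
#' @param seed integer seed of the hash function; sketches are only
#'   comparable when built with the same `k` and `seed`.
#' @param genome_id identifier stored in the sketch.
#' @return an object of class `GenomeSketch`: a list with fields
#'   `genome_id`, `k`, `sketch_size`, `seed`, `hashes` (strictly increasing
#'   numeric vector), and `genome_length`.
#' @examples
#' sk <- build_sketch("ACGTACGTACGTACGTACGTACGT", k = 4, sketch_size = 100)
#' length(sk$hashes)
#' @export
build_sketch <- function(sequence, k = 21L, sketch_size = 1000L, seed = 42L,
                         genome_id = "genome") {
    if (k <= 1L) stop("k must be at least 2")
    if (sketch_size < 1L) stop("sketch_size must be positive")
    seqs <- .as_seqs(sequence)
    usable <- nchar(seqs) >= k
    if (!any(usable))
        stop("empty sketch: no record of length >= k (", k, ")")
    hashes <- sort(unique(unlist(lapply(
        seqs[usable], .canonical_kmer_hashes, k = as.integer(k),
        seed = as.numeric(seed)), use.names = FALSE)))
    hashes <- hashes[seq_len(min(length(hashes), sketch_size))]
    structure(list(genome_id = genome_id, k = as.integer(k),
                   sketch_size = as.integer(sketch_size),
                   seed = as.integer(seed), hashes = hashes,
                   genome_length = sum(nchar(seqs))),
              class = "GenomeSketch")
}

#' @export
print.GenomeSketch <- function(x, ...) {
    cat(sprintf("GenomeSketch %s: k=%d, %d/%d hashes, %d bp\n",
                x$genome_id, x$k, length(x$hashes), x$sketch_size,
                x$genome_length))
    invisible(x)
}

#' Mash-style similarity between two sketches
#'
#' Estimates the Jaccard similarity of two genomes' canonical k-mer sets
#' from their bottom-s sketches using the merged bottom-s convention: the s
#' smallest hashes of the sketch union form the sample, and the Jaccard
#' estimate is the fraction of that sample present in both sketches. The
#' Mash identity is `1 - d` with distance
#' `d = -(1/k) * log(2j / (1 + j))`, clamped to `[0, 1]`; `j = 0` maps to
#' identity 0.
#'
#' When `sketch_size` is at least the number of distinct canonical k-mers in
#' both genomes the estimate equals the exact Jaccard of the full k-mer
#' sets.
#'
#' @param a,b `GenomeSketch` objects built with the same `k` and hash seed.
#' @return named numeric vector `c(jaccard =, identity =)`.
#' @export
mash_similarity <- function(a, b) {
    stopifnot(inherits(a, "GenomeSketch"), inherits(b, "GenomeSketch"))
    if (a$k != b$k) stop("sketches were built with different k")
    if (a$seed != b$seed) stop("sketches were built with different hash seeds")
    u <- sort(unique(c(a$hashes, b$hashes)))
    m <- min(min(a$sketch_size, b$sketch_size), length(u))
    if (m == 0L) return(c(jaccard = 0, identity = 0))
    top <- u[seq_len(m)]
    shared <- sum(top %in% a$hashes & top %in% b$hashes)
    j <- shared / m
    identity <- if (j <= 0) 0 else {
        d <- -log(2 * j / (1 + j)) / a$k
        min(1, max(0, 1 - d))
    }
    c(jaccard = j, identity = identity)
}

#' Rank candidate homologs by Mash identity
#'
#' Compares the draft sketch against every sketch in a database and returns
#' the top `t` genomes whose Mash identity strictly exceeds `min_identity`,
#' sorted by identity (ties broken by `genome_id`).
#'
#' @param draft `GenomeSketch` of the draft genome.
#' @param database list of `GenomeSketch` objects.
#' @param t maximum number of genomes returned (default 20).
#' @param min_identity retention cutoff, strict (default 0.95).
#' @return data.frame of similarity records with columns `genome_id`,
#'   `mash_jaccard`, `mash_identity`, `ani`, `asi`, `retained`,
#'   `fallback_used`; `ani`/`asi` are `NA` until [fragment_ani()] fills
#'   them.
#' @export
rank_candidates <- function(draft, database, t = 20L, min_identity = 0.95) {
    empty <- data.frame(genome_id = character(), mash_jaccard = numeric(),
                        mash_identity = numeric(), ani = numeric(),
                        asi = numeric(), retained = logical(),
                        fallback_used = logical(),
                        stringsAsFactors = FALSE)
    if (length(database) == 0L) {
        warning("empty sketch database: no candidates to rank")
        return(empty)
    }
    sim <- vapply(database, function(s) mash_similarity(draft, s), numeric(2))
    rec <- data.frame(
        genome_id = vapply(database, `[[`, character(1), "genome_id"),
        mash_jaccard = sim["jaccard", ], mash_identity = sim["identity", ],
        ani = NA_real_, asi = NA_real_, retained = NA,
        fallback_used = FALSE, stringsAsFactors = FALSE)
    rec <- rec[rec$mash_identity > min_identity, , drop = FALSE]
    rec <- rec[order(-rec$mash_identity, rec$genome_id), , drop = FALSE]
    rec <- utils::head(rec, t)
    rownames(rec) <- NULL
    rec
}

#' Read or write a sketch database
#'
#' The database is a versioned flat TSV: one header line recording the
#' sketching parameters, then one line per genome with its id, length and
#' comma-separated hash list. All sketches in one database share `k`,
#' `sketch_size` and hash seed.
#'
#' @param sketches list of `GenomeSketch` objects.
#' @param path file path.
#' @return `read_sketch_db` returns a named list of `GenomeSketch`;
#'   `write_sketch_db` returns `path` invisibly.
#' @export
write_sketch_db <- function(sketches, path) {
    stopifnot(length(sketches) > 0L)
    k <- unique(vapply(sketches, `[[`, integer(1), "k"))
    s <- unique(vapply(sketches, `[[`, integer(1), "sketch_size"))
    seed <- unique(vapply(sketches, `[[`, integer(1), "seed"))
    if (length(k) != 1L || length(s) != 1L || length(seed) != 1L)
        stop("all sketches in a database must share k, sketch_size and seed")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#modpolisher_sketch_db\tv1\tk=%d\tsketch_size=%d\tseed=%d",
                       k, s, seed), con)
    for (sk in sketches)
        writeLines(paste(sk$genome_id, sk$genome_length,
                         paste(sprintf("%.0f", sk$hashes), collapse = ","),
                         sep = "\t"), con)
    invisible(path)
}

#' @rdname write_sketch_db
#' @export
read_sketch_db <- function(path) {
    lines <- readLines(path)
    hdr <- lines[1]
    if (!startsWith(hdr, "#modpolisher_sketch_db"))
        stop("not a modpolisher sketch database: ", path)
    get <- function(key) as.integer(sub(paste0(".*", key, "="), "",
                                        regmatches(hdr, regexpr(paste0(key, "=[0-9]+"), hdr))))
    k <- get("k"); s <- get("sketch_size"); seed <- get("seed")
    out <- lapply(lines[-1], function(ln) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        structure(list(genome_id = f[1], k = k, sketch_size = s, seed = seed,
                       hashes = as.numeric(strsplit(f[3], ",", fixed = TRUE)[[1]]),
                       genome_length = as.integer(f[2])),
                  class = "GenomeSketch")
    })
    names(out) <- vapply(out, `[[`, character(1), "genome_id")
    out
}

#' Sketch every FASTA file in a directory
#'
#' One sketch per file; multi-record files are pooled per file. The file
#' name (without extension) becomes the genome id.
#'
#' @param dir directory containing `.fa`/`.fasta`/`.fna` files.
#' @inheritParams build_sketch
#' @return named list of `GenomeSketch` objects.
#' @export
build_sketch_db <- function(dir, k = 21L, sketch_size = 1000L, seed = 42L) {
    files <- list.files(dir, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files found in ", dir)
    out <- lapply(files, function(f)
        build_sketch(f, k = k, sketch_size = sketch_size, seed = seed,
                     genome_id = tools::file_path_sans_ext(basename(f))))
    names(out) <- vapply(out, `[[`, character(1), "genome_id")
    out
}
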