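# one-locus matrix builder: draft base, read counts, homolog counts, quality
locus1 <- function(draft = "T", reads = c(0, 0, 0, 0), homs = c(0, 0, 0, 0),
                   qual = 10) {
    toy_matrix(draft, matrix(as.integer(reads), 4),
               matrix(as.integer(homs), 4), qual)
}

test_that("candidate thresholds are strict inequalities", {
    # discordancy exactly 0.05 (1 of 20) fails '> 0.05'
    m <- locus1(draft = "C", reads = c(1, 19, 0, 0), homs = c(20, 0, 0, 0),
                qual = 12)
    expect_equal(nrow(find_candidates(m)), 0)
    # discordancy 0.10 with quality 12 passes both
    m <- locus1(draft = "C", reads = c(2, 18, 0, 0), homs = c(20, 0, 0, 0),
                qual = 12)
    expect_equal(nrow(find_candidates(m)), 1)
    # mean quality exactly 15 fails '< 15'
    m <- locus1(draft = "C", reads = c(2, 18, 0, 0), homs = c(20, 0, 0, 0),
                qual = 15)
    expect_equal(nrow(find_candidates(m)), 0)
})

test_that("depth floors gate candidacy and are counted", {
    m <- locus1(draft = "C", reads = c(1, 3, 0, 0), homs = c(20, 0, 0, 0),
                qual = 8)  # read depth 4 < 5
    cand <- find_candidates(m)
    expect_equal(nrow(cand), 0)
    expect_equal(attr(cand, "n_skipped_depth"), 1)
    m <- locus1(draft = "C", reads = c(4, 12, 0, 0), homs = c(2, 0, 0, 0),
                qual = 8)  # homolog depth 2 < 3
    expect_equal(nrow(find_candidates(m)), 0)
})

test_that("homolog consensus and conservation follow max/sum with NA ties", {
    expect_equal(homolog_conservation(c(0, 20, 0, 0)),
                 list(consensus = "C", conservation = 1.0))
    expect_equal(homolog_conservation(c(0, 19, 0, 1)),
                 list(consensus = "C", conservation = 0.95))
    tie <- homolog_conservation(c(0, 10, 0, 10))
    expect_true(is.na(tie$consensus))
    expect_equal(tie$conservation, 0.5)
    zero <- homolog_conservation(c(0, 0, 0, 0))
    expect_true(is.na(zero$consensus))
    expect_true(is.na(zero$conservation))
})

test_that("fully conserved homologs drive a default-mode correction", {
    m <- locus1(draft = "T", reads = c(0, 4, 0, 12), homs = c(0, 20, 0, 0),
                qual = 9)
    res <- apply_corrections(m, find_candidates(m))
    expect_equal(res$report$n_corrections, 1)
    expect_equal(res$sequence, "C")
    corr <- res$report$corrections
    expect_equal(corr$old_allele, "T")
    expect_equal(corr$new_allele, "C")
    expect_equal(corr$mode, "default")
    expect_equal(corr$read_support_of_new_allele, 4 / 16)
})

test_that("95% conservation blocks default mode but passes motif mode", {
    m <- locus1(draft = "T", reads = c(0, 4, 0, 12), homs = c(0, 19, 0, 1),
                qual = 9)
    cand <- find_candidates(m)
    res <- apply_corrections(m, cand)
    expect_equal(res$report$n_corrections, 0)
    expect_equal(res$report$skipped$reason, "low_conservation")
    expect_equal(res$sequence, "T")

    # same locus inside a supplied motif occurrence: 0.95 >= 0.8 corrects
    mm <- toy_matrix("GCTGC",
                     read_counts = cbind(c(0L,0L,0L,0L), c(0L,0L,0L,0L),
                                         c(0L,4L,0L,12L), c(0L,0L,0L,0L),
                                         c(0L,0L,0L,0L)),
                     hom_counts = cbind(c(0L,20L,0L,0L), c(0L,0L,0L,20L),
                                        c(0L,19L,0L,1L), c(0L,0L,20L,0L),
                                        c(0L,20L,0L,0L)),
                     mean_qual = rep(9, 5))
    # only position 3 is discordant; GCWGC covers it (GCTGC matches W=T)
    cand <- find_candidates(mm, min_read_depth = 5, min_homolog_depth = 3)
    expect_equal(cand$position, 2L)
    res <- apply_corrections(mm, cand, motif = "GCWGC")
    expect_equal(res$report$n_corrections, 1)
    expect_equal(res$report$corrections$mode, "motif")
    expect_equal(res$sequence, "GCCGC")
})

test_that("the replacement allele must be observed among read alleles", {
    # homologs say G, but no read carries G
    m <- locus1(draft = "T", reads = c(4, 0, 0, 12), homs = c(0, 0, 20, 0),
                qual = 9)
    res <- apply_corrections(m, find_candidates(m))
    expect_equal(res$report$n_corrections, 0)
    expect_equal(res$report$skipped$reason, "allele_not_in_reads")
    res2 <- apply_corrections(m, find_candidates(m),
                              allow_unseen_allele = TRUE)
    expect_equal(res2$report$n_corrections, 1)
    expect_equal(res2$sequence, "G")
})

test_that("consensus equal to the draft or tied leaves the draft untouched", {
    m <- locus1(draft = "T", reads = c(0, 4, 0, 12), homs = c(0, 0, 0, 20),
                qual = 9)
    res <- apply_corrections(m, find_candidates(m))
    expect_equal(res$report$n_corrections, 0)
    expect_equal(res$report$skipped$reason, "consensus_equals_draft")

    m <- locus1(draft = "T", reads = c(0, 4, 0, 12), homs = c(0, 10, 0, 10),
                qual = 9)
    res <- apply_corrections(m, find_candidates(m))
    expect_equal(res$report$skipped$reason, "consensus_tie")
})

test_that("unsupported motif characters are rejected", {
    m <- locus1(draft = "T", reads = c(0, 4, 0, 12), homs = c(0, 20, 0, 0),
                qual = 9)
    expect_error(apply_corrections(m, find_candidates(m), motif = "CCRAC"),
                 "unsupported motif")
})

test_that("polish refuses to run without homolog alignments", {
    ts <- small_truth_set(seed = 31)
    expect_error(polish(ts$files$draft, ts$files$reads_sam, character(0)),
                 "homolog")
})

test_that("polish corrects planted errors, spares decoys, and is idempotent", {
    ts <- small_truth_set(seed = 32)
    res <- polish(ts$files$draft, ts$files$reads_sam, ts$files$homolog_sams)
    corr <- res$corrections
    mod <- ts$modified_loci$position
    expect_gte(sum(mod %in% corr$position), length(mod) - 1)
    expect_equal(sum(ts$decoy_variant_loci$position %in% corr$position), 0)
    # corrected loci now match the truth
    hit <- intersect(mod, corr$position)
    expect_equal(
        substring(res$polished[["ctg1"]], hit + 1, hit + 1),
        ts$modified_loci$truth_allele[match(hit, mod)])
    # substitutions only: length preserved
    expect_equal(nchar(res$polished[["ctg1"]]), nchar(ts$draft_genome))

    # second pass over the polished genome with the same reads/homologs
    # (coordinates are stable) applies nothing new
    polished_fa <- tempfile(fileext = ".fa")
    modpolisher:::.write_fasta(res$polished, polished_fa)
    res2 <- polish(polished_fa, ts$files$reads_sam, ts$files$homolog_sams)
    expect_equal(nrow(res2$corrections), 0)
})

test_that("stricter thresholds never increase the correction count", {
    ts <- small_truth_set(seed = 33)
    n_at <- function(disc, qmax) {
        nrow(polish(ts$files$draft, ts$files$reads_sam,
                    ts$files$homolog_sams, discordancy_min = disc,
                    quality_max = qmax)$corrections)
    }
    base <- n_at(0.05, 15)
    expect_lte(n_at(0.15, 15), base)
    expect_lte(n_at(0.05, 10), base)
    expect_lte(n_at(0.35, 8), min(n_at(0.35, 15), n_at(0.05, 8)))
})

test_that("without full conservation and without motif, output = input", {
    # homologs split 0.9/0.1 at every planted locus: specificity first
    ts <- small_truth_set(seed = 34, n_homologs = 10)
    # rewrite one homolog so every modified locus loses full conservation
    hs <- ts$files$homolog_sams
    hom1 <- strsplit(ts$homolog_genomes[1], "")[[1]]
    p1 <- ts$modified_loci$position + 1
    hom1[p1] <- ts$modified_loci$draft_allele  # agrees with the draft error
    modpolisher:::.write_hom_sam("homolog_01", paste(hom1, collapse = ""),
                                 "ctg1", length(hom1), hs[1])
    res <- polish(ts$files$draft, ts$files$reads_sam, hs)
    expect_equal(sum(res$corrections$position %in% ts$modified_loci$position), 0)
    expect_equal(res$polished[["ctg1"]], ts$draft_genome)
})
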