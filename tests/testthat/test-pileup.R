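draft20 <- c(ctg = "ACGTACGTACGTACGTACGT")

test_that("unanimous read pileup gives the planted counts and quality", {
    recs <- vapply(1:10, function(i)
        sam_record(paste0("r", i), pos = 5, seq = "C",
                   qual = qstring(30)), character(1))
    pm <- pileup_from_read_alignments(draft20, write_sam(recs, len = 20))
    expect_equal(unname(pm$read_counts[, 5]), c(0, 10, 0, 0))
    expect_equal(mean_quality(pm)[5], 30)
    expect_equal(sum(pm$read_counts), 10)
})

test_that("deletions and insertions contribute nothing to spanned positions", {
    # 5M2D5M starting at 1: bases land on 1-5 and 8-12, nothing on 6-7
    r1 <- sam_record("del", pos = 1, seq = "ACGTAGTACG",
                     cigar = "5M2D5M", qual = qstring(rep(20, 10)))
    # 3M2I3M starting at 1: 6 reference positions, insertion skipped
    r2 <- sam_record("ins", pos = 1, seq = "ACGTTTAC",
                     cigar = "3M2I3M", qual = qstring(rep(20, 8)))
    pm <- pileup_from_read_alignments(draft20, write_sam(c(r1, r2), len = 20))
    depth <- colSums(pm$read_counts)
    # deleted positions 6-7 get nothing from the 5M2D5M read; position 6 is
    # still covered by the 3M2I3M read (reference span 6)
    expect_equal(unname(depth[6:7]), c(1, 0))
    expect_equal(unname(depth[1:5]), rep(2, 5))
    expect_equal(unname(depth[8:12]), rep(1, 5))
    expect_equal(sum(depth), 10 + 6)            # M/=/X lengths only
})

test_that("mean quality is the arithmetic mean of Phred scores", {
    recs <- c(sam_record("a", pos = 3, seq = "A", qual = qstring(10)),
              sam_record("b", pos = 3, seq = "A", qual = qstring(10)),
              sam_record("c", pos = 3, seq = "G", qual = qstring(40)))
    pm <- pileup_from_read_alignments(draft20, write_sam(recs, len = 20))
    expect_equal(unname(pm$read_counts[c("A", "G"), 3]), c(2, 1))
    expect_equal(mean_quality(pm)[3], 20)
    # probability-space averaging is dominated by the worst base
    expect_lt(mean_quality(pm, "probability")[3], 15)
    # mean lies within [min, max] of contributing scores
    expect_gte(mean_quality(pm)[3], 10)
    expect_lte(mean_quality(pm)[3], 40)
})

test_that("reads generated error-free from the draft are concordant", {
    set.seed(8)
    g <- c(ctg = random_genome(300))
    recs <- vapply(1:30, function(i) {
        s <- sample(250, 1)
        sam_record(paste0("r", i), pos = s,
                   seq = substr(g[[1]], s, s + 49),
                   qual = qstring(rep(25, 50)))
    }, character(1))
    pm <- pileup_from_read_alignments(g, write_sam(recs, len = 300))
    depth <- colSums(pm$read_counts)
    disc <- allele_discordancy(pm$read_counts)
    expect_true(all(disc[depth > 0] == 0))
    expect_equal(sum(depth), 30 * 50)
})

test_that("records without qualities are skipped with a warning", {
    recs <- c(sam_record("ok", pos = 1, seq = "ACGT",
                         qual = qstring(rep(20, 4))),
              sam_record("noq", pos = 1, seq = "ACGT", qual = "*"))
    expect_warning(
        pm <- pileup_from_read_alignments(draft20, write_sam(recs, len = 20)),
        "without base qualities")
    expect_equal(sum(pm$read_counts), 4)
})

test_that("unknown SAM reference names are reported by name", {
    recs <- sam_record("r", pos = 1, seq = "ACGT", contig = "plasmidX",
                       qual = qstring(rep(20, 4)))
    expect_error(
        pileup_from_read_alignments(draft20,
                                    write_sam(recs, contig = "plasmidX",
                                              len = 20)),
        "plasmidX")
})

test_that("malformed CIGAR records are skipped, not fatal", {
    good <- sam_record("g", pos = 1, seq = "ACGT", qual = qstring(rep(20, 4)))
    bad <- sam_record("b", pos = 1, seq = "ACGT", qual = qstring(rep(20, 4)),
                      cigar = "4Q")
    expect_warning(
        pm <- pileup_from_read_alignments(draft20,
                                          write_sam(c(good, bad), len = 20)),
        "malformed CIGAR")
    expect_equal(sum(pm$read_counts), 4)
})

test_that("homolog counts: per-genome single count, order-invariant", {
    recs <- c(sam_record("homA", pos = 3, seq = "CCCC"),
              sam_record("homB", pos = 3, seq = "CTCC"))
    pm0 <- pileup_from_read_alignments(draft20, write_sam(character(), len = 20))
    pm <- pileup_add_homologs(pm0, write_sam(recs, len = 20))
    expect_equal(unname(pm$hom_counts[, 4]), c(0, 1, 0, 1))  # C vs T
    cons <- homolog_conservation(pm$hom_counts[, 4])
    expect_true(is.na(cons$consensus))
    expect_equal(cons$conservation, 0.5)
    # position not covered by homB's alignment gets only homA's count
    expect_equal(sum(pm$hom_counts[, 10]), 0)
    expect_equal(pm$n_homolog_tracks, 2)

    # record order must not matter
    pm_rev <- pileup_add_homologs(pm0, write_sam(rev(recs), len = 20))
    expect_identical(pm$hom_counts, pm_rev$hom_counts)

    # duplicated/overlapping alignments of one genome count once
    dup <- c(sam_record("homA", pos = 3, seq = "CCCC"),
             sam_record("homA", pos = 5, seq = "CCCC"))
    pm_dup <- pileup_add_homologs(pm0, write_sam(dup, len = 20))
    expect_true(all(pm_dup$hom_counts["C", 3:8] == 1))
})

test_that("secondary alignments are excluded from read pileups", {
    recs <- c(sam_record("r", pos = 1, seq = "ACGT",
                         qual = qstring(rep(20, 4))),
              sam_record("r", pos = 9, seq = "ACGT",
                         qual = qstring(rep(20, 4)), flag = 256L))
    pm <- pileup_from_read_alignments(draft20, write_sam(recs, len = 20))
    expect_equal(sum(pm$read_counts), 4)
})

test_that("allele discordancy follows 1 - max/sum", {
    expect_equal(allele_discordancy(c(0, 20, 0, 0)), 0)
    expect_equal(allele_discordancy(c(1, 19, 0, 0)), 0.05)
    expect_equal(allele_discordancy(c(5, 5, 5, 5)), 0.75)
    expect_true(is.na(allele_discordancy(c(0, 0, 0, 0))))
    m <- cbind(c(0, 20, 0, 0), c(5, 5, 5, 5))
    expect_equal(allele_discordancy(m), c(0, 0.75))
})

test_that("aligner round-trip reproduces planted pileup counts", {
    ts <- small_truth_set(seed = 21)
    sam <- align_reads(ts$files$reads_fastq, ts$files$draft)
    pm <- pileup_from_read_alignments(ts$files$draft, sam)
    pm_pre <- pileup_from_read_alignments(ts$files$draft,
                                          ts$files$reads_sam)
    # minimap2 re-derives what the generator planted: same major allele and
    # near-identical counts at the planted modified loci (a handful of read
    # ends may be soft-clipped by the aligner)
    p1 <- ts$modified_loci$position + 1
    expect_equal(apply(pm$read_counts[, p1], 2, which.max),
                 apply(pm_pre$read_counts[, p1], 2, which.max))
    expect_lte(sum(abs(pm$read_counts[, p1] - pm_pre$read_counts[, p1])),
               ceiling(0.02 * sum(pm_pre$read_counts[, p1])))
})
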