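test_that("deletion lengths follow 1-based inclusive arithmetic", {
  expect_equal(deletion_length(deletion_variant(658389, 658472)), 84)
  expect_equal(deletion_length(deletion_variant(5, 5)), 1)
  expect_equal(deletion_length(deletion_variant(934, 1002)), 69)
  expect_equal(deletion_length(deletion_variant()), 0)
})

test_that("deletions excise exactly the stated interval", {
  expect_equal(apply_deletion("ACGTACGTAC", deletion_variant(5, 8)), "ACGTAC")
  expect_equal(apply_deletion("ACGTACGTAC", deletion_variant()), "ACGTACGTAC")
  expect_error(apply_deletion("ACGTACGTAC", deletion_variant(5, 11)),
               class = "CoordinateError")
})

test_that("variant strings parse with comma grouping", {
  v <- parse_variant("chrE22C19W28_E50C23:658,389-658,472")
  expect_equal(deletion_length(v), 84)
  expect_error(parse_variant("oops"), class = "ParseError")
})

test_that("junction damage is classified per junction", {
  g <- krt75_like_gene(seed = 1)
  dmg <- classify_junction_damage(g$model, g$variant)
  expect_equal(dmg$junctions$donor[5], "lost")
  expect_true(all(dmg$junctions$donor[-5] == "intact"))
  expect_true(all(dmg$junctions$acceptor == "intact"))
  expect_equal(dmg$exons_truncated, 5L)
  # deletion wholly inside an intron, away from both junctions
  i3 <- g$model$exons$end[3] + c(20, 30)
  dmg2 <- classify_junction_damage(g$model, deletion_variant(i3[1], i3[2]))
  expect_true(all(dmg2$junctions$donor == "intact"))
  expect_true(all(dmg2$junctions$acceptor == "intact"))
  expect_length(dmg2$exons_truncated, 0)
  # deletion covering an entire internal exon affects both flanking junctions
  ex3 <- g$model$exons[3, ]
  dmg3 <- classify_junction_damage(g$model,
                                   deletion_variant(ex3$start - 1, ex3$end + 1))
  expect_equal(dmg3$junctions$donor[3], "lost")
  expect_equal(dmg3$junctions$acceptor[2], "lost")
  expect_true(3 %in% dmg3$exons_truncated)
})

test_that("cryptic-donor scan scores, ranks and errors as documented", {
  g <- krt75_like_gene(seed = 2)
  cand <- find_cryptic_donor(g$model, g$variant)
  expect_equal(nrow(cand), 1)       # unique GT in that exon by construction
  expect_equal(cand$hexamer, "GTGAAG")
  expect_equal(cand$offset_nt, 69)
  # score 6/6 when the authentic donor hexamer is GTGAAG itself
  g2 <- generate_gene(gene_spec(c(60, 99), 40, donor_motif = "GTGAAG",
                                cryptic_site = list(exon = 1, offset = 30,
                                                    hexamer = "GTGAAG"),
                                seed = 3))
  v2 <- deletion_variant(g2$model$exons$end[1] - 2, g2$model$exons$end[1] + 10)
  c2 <- find_cryptic_donor(g2$model, v2)
  expect_equal(c2$score[1], 6L)
  # no lost donor -> error; intronic deletion cannot activate anything
  expect_error(find_cryptic_donor(g2$model,
                                  deletion_variant(g2$model$exons$end[1] + 15,
                                                   g2$model$exons$end[1] + 20)),
               class = "NoLostJunction")
  # tie on score resolved by proximity to the junction
  seqs <- paste0(paste(rep("A", 20), collapse = ""), "GTGAAG",      # offset 94
                 paste(rep("C", 54), collapse = ""), "GTGAAG",      # offset 34
                 paste(rep("A", 28), collapse = ""),                # exon1: 114
                 "GTGAAG", paste(rep("C", 30), collapse = ""), "AG", # intron
                 paste(rep("A", 60), collapse = ""))
  mdl <- gene_model("tie", seqs, data.frame(start = c(1, 153),
                                            end = c(114, 212)),
                    cds_start = 1, cds_end = 174, donor_motif = "GTGAAG")
  vt <- deletion_variant(113, 130)
  ct <- find_cryptic_donor(mdl, vt)
  expect_equal(ct$score[1:2], c(6L, 6L))
  expect_lt(ct$offset_nt[1], ct$offset_nt[2])
})

test_that("the KRT75-like deletion reproduces the printed consequence", {
  g <- krt75_like_gene(seed = 4)
  out <- splice_mutant(g$model, g$variant, find_cryptic_donor(g$model, g$variant))
  expect_equal(out$cds_deletion_interval, c(934, 1002))
  expect_equal(out$cds_deletion_length_nt, 69)
  expect_true(out$in_frame)
  expect_false(out$frameshift)
  expect_equal(out$protein_deletion_interval, c(311, 333))
  expect_equal(out$protein_deletion_length_aa, 23)
})

test_that("intronic deletions leave the mRNA untouched", {
  g <- krt75_like_gene(seed = 5)
  wt <- splice_mutant(g$model, deletion_variant())
  i2 <- g$model$exons$end[2] + c(15, 25)
  out <- splice_mutant(g$model, deletion_variant(i2[1], i2[2]))
  expect_identical(out$mutant_mrna, wt$mutant_mrna)
  expect_equal(out$cds_deletion_length_nt, 0)
  expect_true(out$in_frame)
})

test_that("a candidate downstream of the deletion is invalid", {
  g <- krt75_like_gene(seed = 6)
  fake <- data.frame(pos = g$model$exons$end[5] + 5, hexamer = "GTAAGT",
                     score = 6L, offset_nt = -4)
  expect_error(splice_mutant(g$model, g$variant, fake),
               class = "InvalidCandidate")
})

test_that("losing the donor with no cryptic rescue retains the intron", {
  g <- generate_gene(gene_spec(c(90, 120), 60, seed = 7))   # no cryptic site
  ex1_end <- g$model$exons$end[1]
  v <- deletion_variant(ex1_end - 2, ex1_end + 8)
  out <- splice_mutant(g$model, v, candidate = NULL)
  expect_true(out$intron_retained)
  expect_gt(nchar(out$mutant_mrna), 90 + 120 - 11)
})

test_that("amplicon lengths shrink by the overlapping deletion", {
  v <- deletion_variant(658389, 658472)
  a <- amplicon_lengths(851, v)
  expect_equal(c(a$wt_len, a$mut_len), c(851, 767))
  b <- amplicon_lengths(c(700000, 700850), v)
  expect_equal(b$mut_len, 851)
  cc <- amplicon_lengths(c(658300, 659150), v, fwd_primer = c(658380, 658400))
  expect_true(cc$unreliable_primer)
  expect_equal(cc$mut_len, 851 - 84)
})

test_that("frame law: in-frame exactly when the lost mRNA is a multiple of 3", {
  # conservation checked alongside: mutant mRNA length drops by the cut
  for (off in c(9, 33, 48, 69, 70, 71)) {
    g <- generate_gene(gene_spec(c(120, 150, 90), c(60, 60),
                                 cryptic_site = list(exon = 2, offset = off,
                                                     hexamer = "GTGAAG"),
                                 seed = off))
    ex2_end <- g$model$exons$end[2]
    v <- deletion_variant(ex2_end + 1, ex2_end + 6)   # donor motif only
    out <- splice_mutant(g$model, v, find_cryptic_donor(g$model, v))
    expect_equal(out$cds_deletion_length_nt, off)
    expect_equal(out$in_frame, off %% 3 == 0)
    expect_equal(nchar(out$mutant_mrna), 120 + 150 + 90 - off)
    if (off %% 3 == 0)
      expect_equal(out$protein_deletion_length_aa, off / 3)
    else
      expect_true(out$frameshift)
  }
})

test_that("planted cryptic sites are always top-ranked on random genes", {
  for (s in 1:100) {
    set.seed(s)
    nex <- sample(2:4, 1)
    exl <- 3 * sample(30:80, nex, replace = TRUE)
    ex <- sample(nex - 1, 1)                 # an exon with a downstream donor
    off <- 3 * sample(3:min(30, exl[ex] %/% 3 - 2), 1)
    g <- generate_gene(gene_spec(exl, rep(50, nex - 1),
                                 cryptic_site = list(exon = ex, offset = off,
                                                     hexamer = "GTGAAG"),
                                 seed = s))
    exe <- g$model$exons$end[ex]
    v <- deletion_variant(exe - 2, exe + 8)
    cand <- find_cryptic_donor(g$model, v, lost_intron = ex)
    expect_equal(cand$offset_nt[1], off)
  }
})
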