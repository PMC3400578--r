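test_that("generated gene has the requested exon/intron arithmetic", {
  g <- generate_gene(gene_spec(exon_lengths = c(100, 200),
                               intron_lengths = 50, cds_start = 1, seed = 3))
  expect_equal(nchar(g$model$sequence), 350)
  expect_equal(sum(g$model$exons$end - g$model$exons$start + 1), 300)
  # donor motif at the start of the intron, AG at its end
  intron <- substr(g$model$sequence, 101, 150)
  expect_true(startsWith(intron, "GTAAGT"))
  expect_true(endsWith(intron, "AG"))
})

test_that("inconsistent exon/intron counts are rejected", {
  expect_error(gene_spec(exon_lengths = c(100, 200), intron_lengths = c(50, 50)),
               class = "InvalidSpec")
  expect_error(gene_spec(exon_lengths = 100, intron_lengths = integer(),
                         cds_start = 3),  # CDS of 98 nt: not a multiple of 3
               class = "InvalidSpec")
  expect_error(gene_spec(c(30, 30), 40,
                         cryptic_site = list(exon = 1, offset = 35,
                                             hexamer = "GTGAAG")),
               class = "InvalidSpec")
  # an offset below 6 collides with the authentic junction
  expect_error(gene_spec(c(30, 30), 40,
                         cryptic_site = list(exon = 1, offset = 3,
                                             hexamer = "GTGAAG")),
               class = "InvalidSpec")
})

test_that("KRT75-like preset plants GTGAAG as the unique cryptic donor", {
  g <- krt75_like_gene(seed = 9)
  ex5 <- g$model$exons[5, ]
  exon_seq <- substr(g$model$sequence, ex5$start, ex5$end)
  # hexamer 69 nt upstream of the junction: exonic position E - 69 + 1
  p <- nchar(exon_seq) - 69 + 1
  expect_equal(substr(exon_seq, p, p + 5), "GTGAAG")
  # unique GT dinucleotide in the exon
  gt <- gregexpr("GT", exon_seq, fixed = TRUE)[[1]]
  expect_equal(as.integer(gt), p)
})

test_that("re-splicing the wild-type gene returns exactly the concatenated exons", {
  for (s in 1:3) {
    g <- generate_gene(gene_spec(c(120, 90, 150), c(60, 45), seed = s))
    wt_exons <- paste(substring(g$model$sequence, g$model$exons$start,
                                g$model$exons$end), collapse = "")
    out <- splice_mutant(g$model, deletion_variant())
    expect_identical(out$mutant_mrna, wt_exons)
    expect_false(out$frameshift)
  }
})

test_that("gene generation is seed-deterministic and alphabet-clean", {
  sp <- gene_spec(c(90, 120), 50, seed = 11)
  expect_identical(generate_gene(sp)$model$sequence,
                   generate_gene(sp)$model$sequence)
  expect_true(grepl("^[ACGT]+$", generate_gene(sp)$model$sequence))
})
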