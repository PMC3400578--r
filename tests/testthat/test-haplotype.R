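test_that("full linkage yields a shared run over all markers with no recombinants", {
  ped <- manual_halfsib(n_off = 8, n_markers = 10)
  hs <- haplotype_share(ped)
  expect_equal(length(hs$shared_run), 10)
  expect_equal(unname(hs$shared_interval), c("M1", "M10"))
  expect_equal(nrow(hs$recombinants), 0)
  expect_true(all(hs$per_offspring$consistent))
})

test_that("a planted paternal recombination is reported with its breakpoint", {
  pat <- matrix(1L, 8, 10)
  pat[3, 7:10] <- 2L                  # bird O3 switches between markers 6 and 7
  hs <- haplotype_share(manual_halfsib(pat_allele = pat))
  expect_equal(hs$recombinants$id, "O3")
  expect_equal(hs$recombinants$breakpoint_left, "M6")
  expect_equal(hs$recombinants$breakpoint_right, "M7")
  # the remaining birds still share the full run
  expect_equal(length(hs$shared_run), 10)
  expect_false(hs$per_offspring$consistent[hs$per_offspring$id == "O3"])
})

test_that("markers without usable maternal information are bridged and logged", {
  ped <- manual_halfsib(n_off = 6, n_markers = 8)
  # marker 4: mother's genotype missing and offspring made heterozygous, so
  # the paternal allele is ambiguous there
  ped$geno[2, 4, ] <- NA
  ped$geno[3:8, 4, 1] <- 1L
  ped$geno[3:8, 4, 2] <- 2L
  expect_message(hs <- haplotype_share(ped), "uninformative")
  expect_true("M4" %in% hs$uninformative_markers)
  expect_equal(length(hs$shared_run), 7)      # bridged, not broken
})

test_that("sharing analysis needs affected offspring", {
  ped <- manual_halfsib(n_off = 4, n_markers = 5,
                        affected = rep(FALSE, 4))
  expect_error(haplotype_share(ped), class = "InsufficientData")
})

test_that("simulated recombinants in a cross are recovered end to end", {
  sim <- simulate_cross(cross_spec(n_dams = 2, offspring_per_dam = 10,
                                   n_markers = 12, theta_true = 0.08,
                                   call_rate = 1, sire_marker_het = TRUE,
                                   seed = 31))
  hs <- haplotype_share(sim$pedigree)
  aff_ids <- sim$pedigree$ind$id[sim$pedigree$ind$affection == 2 &
                                   !is.na(sim$pedigree$ind$father)]
  truth_rec <- sim$truth$recombinant[match(aff_ids, sim$truth$offspring_ids), ]
  has_rec <- rowSums(truth_rec) > 0
  expect_setequal(hs$per_offspring$id[!hs$per_offspring$consistent],
                  aff_ids[has_rec])
})
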