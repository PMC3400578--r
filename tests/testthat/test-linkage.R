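test_that("LOD at theta = 0.5 is identically zero", {
  dm <- disease_model()
  expect_equal(two_point_lod(phase_known_backcross(), 1, dm, 0.5), 0,
               tolerance = 1e-9)
  for (s in c(31, 32)) {
    ped <- random_test_pedigree(s)
    expect_equal(two_point_lod(ped, 1, dm, 0.5), 0, tolerance = 1e-9)
  }
})

test_that("ten phase-known non-recombinant meioses give max LOD of 10 log10 2", {
  lod <- two_point_lod(phase_known_backcross(10), 1, disease_model(), 1e-6)
  expect_equal(lod, 10 * log10(2), tolerance = 1e-4)
  # an obligate recombinant sends LOD(0) to -Inf but not LOD(0.1)
  ped_r <- phase_known_backcross(10, n_recomb = 1)
  expect_equal(two_point_lod(ped_r, 1, disease_model(), 0), -Inf)
  expect_true(is.finite(two_point_lod(ped_r, 1, disease_model(), 0.1)))
})

test_that("variable elimination agrees with full enumeration on random pedigrees", {
  dm <- disease_model()
  worst <- 0
  for (s in 1:60) {
    ped <- random_test_pedigree(s)
    for (th in c(0.1, 0.3)) {
      worst <- max(worst, abs(two_point_lod(ped, 1, dm, th) -
                                oracle_lod(ped, 1, dm, th)))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("more non-recombinant meioses give a higher maximum LOD", {
  dm <- disease_model()
  l10 <- two_point_lod(phase_known_backcross(10), 1, dm, 1e-6)
  l20 <- two_point_lod(phase_known_backcross(20), 1, dm, 1e-6)
  expect_gt(l20, l10)
})

test_that("likelihoods are valid probabilities", {
  dm <- disease_model()
  for (s in c(41, 42, 43)) {
    ped <- random_test_pedigree(s)
    for (th in c(0.05, 0.3, 0.5)) {
      L <- featherkit:::pedigree_likelihood(ped, 1, dm, th)
      expect_gt(L, 0)
      expect_lte(L, 1)
    }
  }
})

test_that("24 phase-known fully linked meioses max their LOD near 24 log10 2", {
  sc <- lod_scan(phase_known_backcross(24), 1, disease_model())
  expect_equal(sc$theta_hat, 0)
  expect_lt(abs(sc$lod_max - 24 * log10(2)), 0.1)
  expect_equal(sc$table$lod[sc$table$theta == 0.5], 0, tolerance = 1e-9)
  # a simulated cross without grandparents: the sire phase is unknown and
  # partially informative dams cost information, but complete linkage still
  # places the maximum at theta = 0
  sim <- simulate_cross(cross_spec(n_dams = 3, offspring_per_dam = 8,
                                   n_markers = 1, theta_true = 0,
                                   marker_allele_freq = 0.02, call_rate = 1,
                                   sire_marker_het = TRUE, seed = 12))
  sc2 <- lod_scan(sim$pedigree, 1, sim$disease_model)
  expect_equal(sc2$theta_hat, 0)
  expect_gt(sc2$lod_max, 4)
  expect_lte(sc2$lod_max, 24 * log10(2))
})

test_that("an uninformative marker gives LOD = 0 across the grid", {
  sim <- simulate_cross(cross_spec(n_dams = 2, offspring_per_dam = 5,
                                   n_markers = 1, theta_true = 0,
                                   marker_allele_freq = 0.999, call_rate = 1,
                                   seed = 2))
  # force all founders homozygous 1/1
  sim$pedigree$geno[, 1, 1] <- 1L
  sim$pedigree$geno[, 1, 2] <- 1L
  sc <- lod_scan(sim$pedigree, 1, sim$disease_model)
  expect_true(all(abs(sc$table$lod) < 1e-9))
})

test_that("null simulations rarely reach interesting LOD scores", {
  lm <- vapply(1:50, function(s) {
    sim <- simulate_cross(cross_spec(n_dams = 2, offspring_per_dam = 6,
                                     n_markers = 1, theta_true = 0.5,
                                     call_rate = 1, sire_marker_het = TRUE,
                                     seed = 1000 + s))
    lod_scan(sim$pedigree, 1, sim$disease_model,
             theta_grid = seq(0, 0.5, by = 0.05))$lod_max
  }, 1)
  expect_lt(median(lm), 0.6)
})

test_that("domain and structure errors are raised", {
  ped <- phase_known_backcross(4)
  expect_error(two_point_lod(ped, 1, disease_model(), 0.7),
               class = "DomainError")
  # consanguineous mating (father-daughter) is refused
  ind <- data.frame(id = c("F", "M", "D1", "X1"),
                    father = c(NA, NA, "F", "F"),
                    mother = c(NA, NA, "M", "D1"),
                    sex = c(1, 2, 2, 1), affection = c(1, 1, 1, 1))
  looped <- pedigree(ind, array(NA_integer_, c(4, 1, 2)))
  expect_error(two_point_lod(looped, 1, disease_model(), 0.1),
               class = "NotSupported")
})

test_that("Mendelian screening flags impossible trios only", {
  trio <- function(fa, mo, ch) {
    ind <- data.frame(id = c("F", "M", "K"), father = c(NA, NA, "F"),
                      mother = c(NA, NA, "M"), sex = c(1, 2, 1),
                      affection = 1)
    geno <- array(NA_integer_, c(3, 1, 2))
    geno[1, 1, ] <- fa; geno[2, 1, ] <- mo; geno[3, 1, ] <- ch
    pedigree(ind, geno)
  }
  expect_equal(nrow(check_mendelian(trio(c(1, 1), c(1, 1), c(1, 2)))), 1)
  for (ch in list(c(1, 1), c(1, 2), c(2, 2)))
    expect_equal(nrow(check_mendelian(trio(c(1, 2), c(1, 2), ch))), 0)
  expect_equal(nrow(check_mendelian(trio(c(1, 1), c(1, 1), c(NA, NA)))), 0)
  # one parent missing: child must still share an allele with the known one
  expect_equal(nrow(check_mendelian(trio(c(NA, NA), c(1, 1), c(2, 2)))), 1)
})

test_that("genotype bookkeeping matches the stated panel arithmetic", {
  expect_equal(expected_genotypes_per_bird(2678, 0.9937), 2661L)
  expect_equal(expected_genotypes_per_bird(2678, 1), 2678L)
  sim <- simulate_cross(cross_spec(n_dams = 1, offspring_per_dam = 3,
                                   n_markers = 20, call_rate = 1, seed = 8))
  gs <- genotyping_summary(sim$pedigree)
  expect_true(all(gs$per_individual$n_called == 20))
  empty <- genotyping_summary(array(NA_integer_, c(3, 0, 2)))
  expect_equal(empty$mean_genotypes, 0)
  expect_equal(empty$n_markers, 0)
})

test_that("segregation bookkeeping sums crosses and tests 1:1", {
  seg <- segregation_summary(affected = c(33, 19), unaffected = c(29, 27))
  expect_equal(seg$total, 108)
  expect_equal(seg$n_affected, 52)
  expect_gt(seg$binom_p, 0.05)    # consistent with 1:1
})
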