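#' Specify a simulated mapping cross
#'
#' One heterozygous carrier sire bred to several wild-type dams; offspring
#' genotyped on a biallelic marker panel. Each marker is transmitted from the
#' sire with recombination fraction `theta_true` relative to the trait locus;
#' the trait is autosomal dominant with complete penetrance.
#'
#' @param n_dams number of wild-type dams.
#' @param offspring_per_dam scalar or per-dam vector of offspring counts.
#' @param n_markers number of markers.
#' @param theta_true recombination fraction(s) between the trait locus and
#'   each marker, in \[0, 0.5\] (scalar recycled).
#' @param marker_allele_freq founder frequency of marker allele 1, in (0,1).
#' @param call_rate genotype call rate in (0, 1\]; genotypes are masked to
#'   missing independently at rate `1 - call_rate`.
#' @param disease_allele_freq population disease allele frequency attached to
#'   the disease model (default 0.001).
#' @param sire_marker_het force the sire heterozygous (1/2) at every marker,
#'   making each marker fully informative for paternal transmissions.
#' @param seed integer seed.
#' @return Object of class `cross_spec`.
#' @export
cross_spec <- function(n_dams = 5, offspring_per_dam = c(8, 8, 8, 8, 7),
                       n_markers = 2678, theta_true = 0.5,
                       marker_allele_freq = 0.5, call_rate = 0.9937,
                       disease_allele_freq = 0.001,
                       sire_marker_het = FALSE, seed = 1L) {
  fk_assert(n_dams >= 1, "InvalidSpec", "need at least one dam")
  if (length(offspring_per_dam) == 1)
    offspring_per_dam <- rep(offspring_per_dam, n_dams)
  fk_assert(length(offspring_per_dam) == n_dams, "InvalidSpec",
            "offspring_per_dam must have length 1 or n_dams")
  fk_assert(all(offspring_per_dam >= 1), "InvalidSpec",
            "offspring counts must be positive")
  theta_true <- rep(theta_true, length.out = n_markers)
  fk_assert(all(theta_true >= 0 & theta_true <= 0.5), "InvalidSpec",
            "theta_true must lie in [0, 0.5]")
  fk_assert(marker_allele_freq > 0 && marker_allele_freq < 1, "InvalidSpec",
            "marker_allele_freq must be in (0,1)")
  fk_assert(call_rate > 0 && call_rate <= 1, "InvalidSpec",
            "call_rate must be in (0,1]")
  fk_assert(disease_allele_freq > 0 && disease_allele_freq < 1, "InvalidSpec",
            "disease_allele_freq must be in (0,1)")
  structure(list(n_dams = as.integer(n_dams),
                 offspring_per_dam = as.integer(offspring_per_dam),
                 n_markers = as.integer(n_markers), theta_true = theta_true,
                 marker_allele_freq = marker_allele_freq,
                 call_rate = call_rate,
                 disease_allele_freq = disease_allele_freq,
                 sire_marker_het = isTRUE(sire_marker_het),
                 seed = as.integer(seed)),
            class = "cross_spec")
}

#' Simulate a half-sib mapping cross with known transmission truth
#'
#' The sire is heterozygous (D/d) at the trait locus; dams are homozygous
#' wild type. Offspring receive the sire's trait allele by Mendelian
#' sampling, and at each marker the allele on the same sire haplotype as the
#' transmitted trait allele with probability `1 - theta_true` (the other
#' haplotype's allele with probability `theta_true`). Maternal marker alleles
#' are drawn from each dam's genotype. Affection is determined by carrying
#' the mutant allele (complete penetrance). Genotype calls are masked to
#' missing independently at rate `1 - call_rate`.
#'
#' @param spec a [cross_spec()].
#' @return List with `pedigree` (a [pedigree()]; affection 2 = affected),
#'   `disease_model` (the attached [disease_model()]), and `truth`:
#'   `sire_haps` (2 x m allele matrix, row 1 = haplotype carrying D),
#'   `carrier` (logical per offspring), `recombinant` (offspring x m logical
#'   matrix of sire meioses), `paternal_allele` (offspring x m).
#' @export
simulate_cross <- function(spec) {
  fk_assert(inherits(spec, "cross_spec"), "InvalidSpec",
            "spec must be a cross_spec")
  m <- spec$n_markers
  with_seed(child_seed(spec$seed, "cross"), {
    draw_allele <- function(n) {
      ifelse(runif(n) < spec$marker_allele_freq, 1L, 2L)
    }
    sire_haps <- if (spec$sire_marker_het) {
      rbind(rep(1L, m), rep(2L, m))
    } else rbind(draw_allele(m), draw_allele(m))
    dam_haps <- lapply(seq_len(spec$n_dams),
                       function(d) rbind(draw_allele(m), draw_allele(m)))

    n_off <- sum(spec$offspring_per_dam)
    off_dam <- rep(seq_len(spec$n_dams), spec$offspring_per_dam)
    carrier <- runif(n_off) < 0.5            # sire transmits D or d
    recomb <- matrix(runif(n_off * m) <
                       rep(spec$theta_true, each = n_off), n_off, m)
    # sire haplotype index actually transmitted at each marker
    hap_idx <- (!carrier) + 1L               # 1 = D haplotype
    pat_hap <- matrix(hap_idx, n_off, m)
    pat_hap[recomb] <- 3L - pat_hap[recomb]
    pat_allele <- matrix(sire_haps[cbind(as.vector(pat_hap),
                                         rep(seq_len(m), each = n_off))],
                         n_off, m)
    mat_allele <- matrix(0L, n_off, m)
    for (d in seq_len(spec$n_dams)) {
      rows <- which(off_dam == d)
      pick <- matrix(sample(1:2, length(rows) * m, replace = TRUE),
                     length(rows), m)
      mat_allele[rows, ] <- matrix(dam_haps[[d]][cbind(as.vector(pick),
                                                       rep(seq_len(m),
                                                           each = length(rows)))],
                                   length(rows), m)
    }

    ids <- c("S1", paste0("D", seq_len(spec$n_dams)),
             paste0("O", seq_len(n_off)))
    n <- length(ids)
    ind <- data.frame(
      id = ids,
      father = c(NA, rep(NA, spec$n_dams), rep("S1", n_off)),
      mother = c(NA, rep(NA, spec$n_dams), paste0("D", off_dam)),
      sex = c(1L, rep(2L, spec$n_dams),
              sample(1:2, n_off, replace = TRUE)),
      affection = c(2L, rep(1L, spec$n_dams), ifelse(carrier, 2L, 1L)))

    geno <- array(NA_integer_, c(n, m, 2))
    geno[1, , 1] <- sire_haps[1, ]; geno[1, , 2] <- sire_haps[2, ]
    for (d in seq_len(spec$n_dams)) {
      geno[1 + d, , 1] <- dam_haps[[d]][1, ]
      geno[1 + d, , 2] <- dam_haps[[d]][2, ]
    }
    off_rows <- 1 + spec$n_dams + seq_len(n_off)
    geno[off_rows, , 1] <- pat_allele
    geno[off_rows, , 2] <- mat_allele
    if (spec$call_rate < 1) {
      miss <- matrix(runif(n * m) > spec$call_rate, n, m)
      geno[, , 1][miss] <- NA
      geno[, , 2][miss] <- NA
    }
    ped <- pedigree(ind, geno, paste0("M", seq_len(m)))
    list(pedigree = ped,
         disease_model = disease_model(p_D = spec$disease_allele_freq),
         truth = list(sire_haps = sire_haps, carrier = carrier,
                      recombinant = recomb, paternal_allele = pat_allele,
                      offspring_ids = paste0("O", seq_len(n_off))))
  })
}
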