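# Independent brute-force oracle for the two-point pedigree likelihood.
#
# Enumerates the full Cartesian product of per-individual ordered, phased
# two-locus genotypes (16 states each: trait-paternal, trait-maternal,
# marker-paternal, marker-maternal alleles), dropping only states with zero
# phenotype/genotype support (those contribute exactly 0), and sums the joint
# probability row by row. Shares no code with the package's
# variable-elimination engine.

oracle_states <- expand.grid(tp = 1:2, tm = 1:2, mp = 1:2, mm = 1:2)

# P(child receives haplotype (t_child, m_child) from a parent in state g);
# vectorised over equal-length inputs. Parental haplotype 1 = (tp, mp),
# haplotype 2 = (tm, mm).
oracle_gamete_prob <- function(t_child, m_child, tp, tm, mp, mm, theta) {
  (t_child == tp & m_child == mp) * (1 - theta) / 2 +
    (t_child == tp & m_child == mm) * theta / 2 +
    (t_child == tm & m_child == mm) * (1 - theta) / 2 +
    (t_child == tm & m_child == mp) * theta / 2
}

oracle_likelihood <- function(ped, marker_idx, dm, theta,
                              marker_freq = c(0.5, 0.5)) {
  ind <- ped$ind
  n <- nrow(ind)
  st <- oracle_states

  support <- vector("list", n)
  prior <- matrix(1, 16, n)
  for (i in seq_len(n)) {
    pen <- rep(1, 16)
    aff <- ind$affection[i]
    ncop <- (st$tp == 1) + (st$tm == 1)
    f <- dm$penetrance[ncop + 1]
    if (!is.na(aff) && aff == 2) pen <- pen * f
    if (!is.na(aff) && aff == 1) pen <- pen * (1 - f)
    if (dim(ped$geno)[2] >= marker_idx) {
      g <- ped$geno[i, marker_idx, ]
      if (!any(is.na(g))) {
        obs <- sort(g)
        pen <- pen * as.numeric(pmin(st$mp, st$mm) == obs[1] &
                                  pmax(st$mp, st$mm) == obs[2])
      }
    }
    if (is.na(ind$father[i])) {
      pt <- c(dm$p_D, 1 - dm$p_D)
      prior[, i] <- pt[st$tp] * pt[st$tm] *
        marker_freq[st$mp] * marker_freq[st$mm]
    }
    support[[i]] <- which(pen > 0)
    prior[, i] <- prior[, i] * pen
  }

  # transmission probabilities from the oracle's own formula:
  # A[c, g] = P(paternal haplotype of child state c | father state g)
  # B[c, g] = P(maternal haplotype of child state c | mother state g)
  cs <- rep(1:16, times = 16); gs <- rep(1:16, each = 16)
  A <- matrix(oracle_gamete_prob(st$tp[cs], st$mp[cs],
                                 st$tp[gs], st$tm[gs], st$mp[gs], st$mm[gs],
                                 theta), 16, 16)
  B <- matrix(oracle_gamete_prob(st$tm[cs], st$mm[cs],
                                 st$tp[gs], st$tm[gs], st$mp[gs], st$mm[gs],
                                 theta), 16, 16)

  sizes <- vapply(support, length, 1L)
  stopifnot(prod(sizes) <= 5e6)
  grid <- as.matrix(expand.grid(support))
  p <- rep(1, nrow(grid))
  for (i in seq_len(n)) {
    p <- p * prior[grid[, i], i]
    if (!is.na(ind$father[i])) {
      fi <- match(ind$father[i], ind$id)
      mi <- match(ind$mother[i], ind$id)
      p <- p * A[cbind(grid[, i], grid[, fi])] *
        B[cbind(grid[, i], grid[, mi])]
    }
  }
  sum(p)
}

oracle_lod <- function(ped, marker_idx, dm, theta, marker_freq = c(0.5, 0.5)) {
  log10(oracle_likelihood(ped, marker_idx, dm, theta, marker_freq)) -
    log10(oracle_likelihood(ped, marker_idx, dm, 0.5, marker_freq))
}

# random small loop-free pedigree with gene-dropped genotypes; sizes 4..8
random_test_pedigree <- function(seed) {
  set.seed(seed)
  three_gen <- runif(1) < 0.4
  n_kids <- if (three_gen) sample(1:3, 1) else sample(2:6, 1)
  theta_sim <- runif(1, 0, 0.5)
  q <- runif(1, 0.2, 0.8)
  draw_hap <- function(carrier = FALSE) {
    c(t = if (carrier) 1 else 2, m = sample(1:2, 1, prob = c(q, 1 - q)))
  }
  meiosis <- function(h1, h2) {
    first <- sample(1:2, 1)
    hap <- if (first == 1) h1 else h2
    other <- if (first == 1) h2 else h1
    if (runif(1) < theta_sim) c(hap["t"], other["m"]) else hap
  }
  inds <- list(); haps <- list()
  add <- function(id, father, mother, sex, h1, h2) {
    inds[[id]] <<- data.frame(id = id, father = father, mother = mother,
                              sex = sex, affection = NA)
    haps[[id]] <<- list(h1 = h1, h2 = h2)
  }
  if (three_gen) {
    add("GF", NA, NA, 1, draw_hap(TRUE), draw_hap())
    add("GM", NA, NA, 2, draw_hap(), draw_hap())
    add("P", "GF", "GM", 1,
        meiosis(haps$GF$h1, haps$GF$h2), meiosis(haps$GM$h1, haps$GM$h2))
    add("S", NA, NA, 2, draw_hap(), draw_hap())
    for (k in seq_len(n_kids))
      add(paste0("K", k), "P", "S", sample(1:2, 1),
          meiosis(haps$P$h1, haps$P$h2), meiosis(haps$S$h1, haps$S$h2))
  } else {
    add("F", NA, NA, 1, draw_hap(runif(1) < 0.7), draw_hap())
    add("M", NA, NA, 2, draw_hap(), draw_hap())
    for (k in seq_len(n_kids))
      add(paste0("K", k), "F", "M", sample(1:2, 1),
          meiosis(haps$F$h1, haps$F$h2), meiosis(haps$M$h1, haps$M$h2))
  }
  ind <- do.call(rbind, inds)
  geno <- array(NA_integer_, c(nrow(ind), 1, 2))
  for (i in seq_len(nrow(ind))) {
    h <- haps[[ind$id[i]]]
    ncop <- (h$h1["t"] == 1) + (h$h2["t"] == 1)
    ind$affection[i] <- if (ncop >= 1) 2L else 1L   # dominant, full penetrance
    if (runif(1) > 0.1) geno[i, 1, ] <- c(h$h1["m"], h$h2["m"])
  }
  pedigree(ind, geno)
}
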