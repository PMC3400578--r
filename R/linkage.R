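#' Pedigree with biallelic marker genotypes
#'
#' @param individuals data.frame with columns `id`, `father`, `mother`
#'   (`NA`/`"0"` for founders; both present or both absent), `sex` (1 male,
#'   2 female), `affection` (2 affected, 1 unaffected, 0/NA unknown).
#' @param genotypes optional array `n x m x 2` of allele codes (1/2, NA for
#'   missing) or a PED-style `n x 2m` matrix of allele pairs (0 = missing).
#' @param markers character vector of marker ids (defaults to `M1..Mm`).
#' @return Object of class `pedigree`.
#' @export
pedigree <- function(individuals, genotypes = NULL, markers = NULL) {
  ind <- as.data.frame(individuals)
  fk_assert(all(c("id", "father", "mother", "sex", "affection") %in%
                  names(ind)), "SchemaError",
            "individuals needs id, father, mother, sex, affection")
  ind$id <- as.character(ind$id)
  fk_assert(!anyDuplicated(ind$id), "SchemaError", "duplicate individual ids")
  norm <- function(x) { x <- as.character(x); x[x %in% c("0", "")] <- NA; x }
  ind$father <- norm(ind$father); ind$mother <- norm(ind$mother)
  fk_assert(all(is.na(ind$father) == is.na(ind$mother)), "SchemaError",
            "both parents must be present or both absent")
  for (p in c("father", "mother")) {
    known <- !is.na(ind[[p]])
    fk_assert(all(ind[[p]][known] %in% ind$id), "SchemaError",
              "unknown %s id", p)
    sx <- ind$sex[match(ind[[p]][known], ind$id)]
    fk_assert(all(sx == if (p == "father") 1 else 2), "SchemaError",
              "%s must have sex %d", p, if (p == "father") 1 else 2)
  }
  # generation depth; also proves the parentage graph acyclic
  depth <- setNames(rep(NA_real_, nrow(ind)), ind$id)
  depth[is.na(ind$father)] <- 0
  for (it in seq_len(nrow(ind) + 1)) {
    todo <- is.na(depth)
    if (!any(todo)) break
    dn <- pmax(depth[ind$father[todo]], depth[ind$mother[todo]]) + 1
    depth[which(todo)[!is.na(dn)]] <- dn[!is.na(dn)]
  }
  fk_assert(!any(is.na(depth)), "SchemaError", "parentage contains a cycle")
  ind$depth <- as.numeric(depth)

  if (is.null(genotypes)) {
    geno <- array(NA_integer_, c(nrow(ind), 0, 2))
    markers <- character()
  } else if (length(dim(genotypes)) == 3) {
    geno <- genotypes
  } else {
    m <- ncol(genotypes) / 2
    fk_assert(m == floor(m), "SchemaError",
              "genotype matrix must have an even number of columns")
    geno <- array(NA_integer_, c(nrow(ind), m, 2))
    g <- as.matrix(genotypes)
    g[g == 0] <- NA
    geno[, , 1] <- g[, 2 * seq_len(m) - 1]
    geno[, , 2] <- g[, 2 * seq_len(m)]
  }
  fk_assert(dim(geno)[1] == nrow(ind), "SchemaError",
            "genotype rows must match individuals")
  if (is.null(markers)) markers <- paste0("M", seq_len(dim(geno)[2]))
  fk_assert(length(markers) == dim(geno)[2], "SchemaError",
            "marker names must match genotype columns")
  structure(list(ind = ind, geno = geno, markers = as.character(markers)),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals (%d founders), %d markers, %d affected\n",
              nrow(x$ind), sum(is.na(x$ind$father)), length(x$markers),
              sum(x$ind$affection == 2, na.rm = TRUE)))
  invisible(x)
}

# consanguinity check: do any two mates share an ancestor?
ped_has_loops <- function(ped) {
  ind <- ped$ind
  anc <- function(id) {
    out <- character()
    frontier <- id
    while (length(frontier)) {
      i <- match(frontier, ind$id)
      frontier <- unique(c(ind$father[i], ind$mother[i]))
      frontier <- frontier[!is.na(frontier) & !(frontier %in% out)]
      out <- c(out, frontier)
    }
    out
  }
  mates <- unique(ind[!is.na(ind$father), c("father", "mother")])
  for (i in seq_len(nrow(mates))) {
    a <- c(mates$father[i], anc(mates$father[i]))
    b <- c(mates$mother[i], anc(mates$mother[i]))
    if (length(intersect(a, b))) return(TRUE)
  }
  FALSE
}

#' Single-locus disease model
#'
#' @param p_D disease allele frequency (default 0.001).
#' @param penetrance probability of affection for 0, 1, 2 copies of the
#'   disease allele; default `c(0, 1, 1)` (autosomal dominant, complete
#'   penetrance).
#' @return Object of class `disease_model`.
#' @export
disease_model <- function(p_D = 0.001, penetrance = c(0, 1, 1)) {
  fk_assert(p_D > 0 && p_D < 1, "InvalidSpec", "p_D must be in (0,1)")
  fk_assert(length(penetrance) == 3 && all(penetrance >= 0 & penetrance <= 1),
            "InvalidSpec", "penetrance must be 3 probabilities (0,1,2 copies)")
  structure(list(p_D = p_D, penetrance = penetrance), class = "disease_model")
}

# --- exact two-locus pedigree likelihood ------------------------------------
#
# Per-individual state: ordered, phased two-locus genotype
#   paternal haplotype hp = (trait allele tp, marker allele mp)
#   maternal haplotype hm = (tm, mm)
# hap index h = 2*(t-1) + m in 1:4; state index s = hm + 4*(hp-1) in 1:16.
# Trait allele 1 = disease (D), 2 = wild type; marker alleles 1/2.

.hap_t <- rep(1:2, each = 2)
.hap_m <- rep(1:2, times = 2)
.state_hp <- rep(1:4, each = 4)
.state_hm <- rep(1:4, times = 4)

# gamete emission matrix: G[h, g] = P(transmit haplotype h | parent state g)
gamete_matrix <- function(theta) {
  G <- matrix(0, 4, 16)
  for (g in 1:16) {
    A <- .state_hp[g]; B <- .state_hm[g]
    tA <- .hap_t[A]; mA <- .hap_m[A]; tB <- .hap_t[B]; mB <- .hap_m[B]
    add <- function(t, m, p) {
      h <- 2 * (t - 1) + m
      G[h, g] <<- G[h, g] + p
    }
    add(tA, mA, (1 - theta) / 2); add(tA, mB, theta / 2)
    add(tB, mB, (1 - theta) / 2); add(tB, mA, theta / 2)
  }
  G
}

# per-individual likelihood vector over the 16 states
state_support <- function(aff, geno_ab, dm) {
  tp <- .hap_t[.state_hp]; tm <- .hap_t[.state_hm]
  mp <- .hap_m[.state_hp]; mm <- .hap_m[.state_hm]
  ncopies <- (tp == 1) + (tm == 1)
  f <- dm$penetrance[ncopies + 1]
  pen <- rep(1, 16)
  if (!is.na(aff) && aff == 2) pen <- f
  if (!is.na(aff) && aff == 1) pen <- 1 - f
  if (!any(is.na(geno_ab))) {
    obs <- sort(geno_ab)
    ok <- (pmin(mp, mm) == obs[1]) & (pmax(mp, mm) == obs[2])
    pen <- pen * ok
  }
  pen
}

founder_prior <- function(dm, marker_freq) {
  pt <- c(dm$p_D, 1 - dm$p_D)
  tp <- .hap_t[.state_hp]; tm <- .hap_t[.state_hm]
  mp <- .hap_m[.state_hp]; mm <- .hap_m[.state_hm]
  pt[tp] * pt[tm] * marker_freq[mp] * marker_freq[mm]
}

# generic discrete factors over 16-state variables
factor_mult <- function(f1, f2) {
  vars <- c(f1$vars, setdiff(f2$vars, f1$vars))
  k <- length(vars)
  a1 <- array(f1$arr, dim = rep(16, k))
  ord2 <- c(f2$vars, setdiff(vars, f2$vars))
  a2 <- array(f2$arr, dim = rep(16, k))
  a2 <- aperm(a2, match(vars, ord2))
  list(vars = vars, arr = a1 * a2)
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  k <- length(f$vars)
  if (k == 1) return(list(vars = character(), arr = sum(f$arr)))
  perm <- c(setdiff(seq_len(k), i), i)
  a <- aperm(array(f$arr, rep(16, k)), perm)
  list(vars = f$vars[perm[-k]],
       arr = array(rowSums(matrix(a, ncol = 16)), rep(16, k - 1)))
}

# exact likelihood of observed phenotypes + marker genotypes for one marker
pedigree_likelihood <- function(ped, marker_idx, dm, theta,
                                marker_freq = c(0.5, 0.5)) {
  ind <- ped$ind
  n <- nrow(ind)
  G <- gamete_matrix(theta)
  prior <- founder_prior(dm, marker_freq)
  unary <- vector("list", n)
  for (i in seq_len(n)) {
    g <- if (dim(ped$geno)[2] >= marker_idx) ped$geno[i, marker_idx, ]
      else c(NA, NA)
    unary[[i]] <- state_support(ind$affection[i], g, dm)
    if (is.na(ind$father[i])) unary[[i]] <- unary[[i]] * prior
  }
  is_parent <- ind$id %in% c(ind$father, ind$mother)
  scalar <- 1

  # fold childless non-founders into 16x16 couple messages
  cmsg <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    if (is_parent[i]) next
    if (is.na(ind$father[i])) {           # disconnected founder
      scalar <- scalar * sum(unary[[i]])
      unary[i] <- list(NULL)
      next
    }
    penM <- matrix(unary[[i]], 4, 4)      # [hm, hp]
    msg <- crossprod(G, t(penM) %*% G)    # rows father, cols mother
    key <- paste(ind$father[i], ind$mother[i], sep = "\r")
    cmsg[[key]] <- if (is.null(cmsg[[key]])) msg else cmsg[[key]] * msg
    unary[i] <- list(NULL)
  }

  # remaining individuals -> generic variable elimination
  active <- which(!vapply(unary, is.null, TRUE))
  factors <- list()
  for (i in active)
    factors[[length(factors) + 1]] <- list(vars = ind$id[i], arr = unary[[i]])
  for (key in ls(cmsg)) {
    fm <- strsplit(key, "\r", fixed = TRUE)[[1]]
    factors[[length(factors) + 1]] <- list(vars = fm, arr = cmsg[[key]])
  }
  for (i in active) {
    if (is.na(ind$father[i])) next
    arr <- array(0, c(16, 16, 16))
    for (s in 1:16)
      arr[s, , ] <- outer(G[.state_hp[s], ], G[.state_hm[s], ])
    factors[[length(factors) + 1]] <-
      list(vars = c(ind$id[i], ind$father[i], ind$mother[i]), arr = arr)
  }

  vars <- unique(unlist(lapply(factors, `[[`, "vars")))
  while (length(vars)) {
    # eliminate the variable with the smallest combined factor
    cost <- vapply(vars, function(v) {
      u <- unique(unlist(lapply(factors,
                                function(f) if (v %in% f$vars) f$vars)))
      length(u)
    }, 1)
    v <- vars[which.min(cost)]
    touch <- vapply(factors, function(f) v %in% f$vars, TRUE)
    comb <- Reduce(factor_mult, factors[touch])
    comb <- factor_marginalize(comb, v)
    factors <- c(factors[!touch], list(comb))
    vars <- setdiff(vars, v)
  }
  for (f in factors) scalar <- scalar * as.numeric(f$arr)
  scalar
}

#' Exact two-point LOD score
#'
#' `LOD(theta) = log10 L(theta) / L(0.5)`, where L is the exact probability
#' of the observed phenotypes and marker genotypes, summed over all founder
#' genotypes (at the stated allele frequencies), phases and transmissions.
#' Computed by variable elimination over phased two-locus genotypes;
#' recombination is sex-averaged. Consanguineous (looped) pedigrees are not
#' supported.
#'
#' @param ped a [pedigree()].
#' @param marker marker id or index.
#' @param dm a [disease_model()].
#' @param theta recombination fraction in \[0, 0.5\].
#' @param marker_freq marker allele frequencies (default 0.5/0.5; marker
#'   frequencies are rarely critical when founder genotypes are observed).
#' @return LOD score (log10). `-Inf` is possible at `theta = 0` with an
#'   obligate recombinant.
#' @export
two_point_lod <- function(ped, marker, dm = disease_model(), theta,
                          marker_freq = c(0.5, 0.5)) {
  fk_assert(is.numeric(theta) && all(theta >= 0 & theta <= 0.5),
            "DomainError", "theta must lie in [0, 0.5]")
  if (ped_has_loops(ped))
    fk_stop("NotSupported", "looped (consanguineous) pedigrees are not supported")
  mi <- if (is.character(marker)) match(marker, ped$markers) else marker
  fk_assert(!is.na(mi) && mi >= 1 && mi <= max(1, dim(ped$geno)[2]),
            "SchemaError", "unknown marker")
  l0 <- pedigree_likelihood(ped, mi, dm, 0.5, marker_freq)
  vapply(theta, function(th) {
    l1 <- pedigree_likelihood(ped, mi, dm, th, marker_freq)
    log10(l1) - log10(l0)
  }, 1)
}

#' LOD scan over a grid of recombination fractions
#'
#' Evaluates [two_point_lod()] on a grid; `theta = 0` is evaluated at 1e-6
#' for numerical safety but reported as 0. The estimate `theta_hat` is the
#' grid argmax (ties resolved toward the smaller theta).
#'
#' @inheritParams two_point_lod
#' @param theta_grid grid of recombination fractions (default 0 to 0.5 by
#'   0.01).
#' @return Object of class `two_point_result`: `marker`, `table` (data.frame
#'   theta, lod), `theta_hat`, `lod_max`.
#' @export
lod_scan <- function(ped, marker, dm = disease_model(),
                     theta_grid = seq(0, 0.5, by = 0.01),
                     marker_freq = c(0.5, 0.5)) {
  eval_grid <- ifelse(theta_grid == 0, 1e-6, theta_grid)
  lods <- two_point_lod(ped, marker, dm, eval_grid, marker_freq)
  i <- which.max(lods)            # which.max returns the first (smallest theta)
  structure(list(marker = if (is.character(marker)) marker else
                   ped$markers[marker],
                 table = data.frame(theta = theta_grid, lod = lods),
                 theta_hat = theta_grid[i], lod_max = lods[i]),
            class = "two_point_result")
}

#' @export
print.two_point_result <- function(x, ...) {
  cat(sprintf("<two_point_result> %s: max LOD %.3f at theta = %.3f\n",
              x$marker, x$lod_max, x$theta_hat))
  invisible(x)
}

#' Mendelian-consistency check
#'
#' Reports every parent-offspring trio whose child genotype is impossible
#' given the parental genotypes at a marker. Missing genotypes are never
#' flagged: a missing parent is treated as compatible with any allele.
#'
#' @param ped a [pedigree()].
#' @param markers marker ids or indices (default: all).
#' @return data.frame with columns `marker`, `child`, `father`, `mother`.
#' @export
check_mendelian <- function(ped, markers = NULL) {
  if (is.null(markers)) markers <- seq_len(dim(ped$geno)[2])
  if (is.character(markers)) markers <- match(markers, ped$markers)
  ind <- ped$ind
  out <- list()
  for (mi in markers) {
    for (i in which(!is.na(ind$father))) {
      ch <- ped$geno[i, mi, ]
      if (any(is.na(ch))) next
      fa <- ped$geno[match(ind$father[i], ind$id), mi, ]
      mo <- ped$geno[match(ind$mother[i], ind$id), mi, ]
      ok <- FALSE
      for (perm in list(ch, rev(ch))) {
        from_f <- any(is.na(fa)) || perm[1] %in% fa
        from_m <- any(is.na(mo)) || perm[2] %in% mo
        if (from_f && from_m) { ok <- TRUE; break }
      }
      if (!ok)
        out[[length(out) + 1]] <- data.frame(marker = ped$markers[mi],
                                             child = ind$id[i],
                                             father = ind$father[i],
                                             mother = ind$mother[i])
    }
  }
  if (!length(out))
    return(data.frame(marker = character(), child = character(),
                      father = character(), mother = character()))
  do.call(rbind, out)
}

#' Genotyping call-rate summary
#'
#' @param x a [pedigree()] or an `n x m x 2` genotype array.
#' @return List: `per_individual` (data.frame id, n_called, call_rate),
#'   `n_markers`, `mean_genotypes`, `mean_call_rate`, `call_rate_range`.
#' @export
genotyping_summary <- function(x) {
  if (inherits(x, "pedigree")) {
    geno <- x$geno; ids <- x$ind$id
  } else {
    geno <- x; ids <- paste0("I", seq_len(dim(x)[1]))
  }
  m <- dim(geno)[2]
  called <- if (m == 0) rep(0L, dim(geno)[1]) else
    rowSums(!is.na(geno[, , 1, drop = FALSE]) &
              !is.na(geno[, , 2, drop = FALSE]), dims = 1)
  cr <- if (m == 0) rep(0, length(called)) else called / m
  list(per_individual = data.frame(id = ids, n_called = as.integer(called),
                                   call_rate = cr),
       n_markers = m,
       mean_genotypes = mean(called),
       mean_call_rate = mean(cr),
       call_rate_range = range(cr))
}

#' Expected genotype calls per individual
#'
#' Deterministic bookkeeping: `round(n_markers * call_rate)`, e.g. a
#' 2678-SNP panel at a 99.37% call rate yields about 2661 genotypes per bird.
#'
#' @param n_markers number of markers on the panel.
#' @param call_rate average genotype call rate in (0, 1\].
#' @return Integer count.
#' @export
expected_genotypes_per_bird <- function(n_markers, call_rate) {
  fk_assert(call_rate > 0 && call_rate <= 1, "InvalidSpec",
            "call_rate must be in (0,1]")
  as.integer(round(n_markers * call_rate))
}

#' Segregation summary for dominant-cross offspring counts
#'
#' For matings of a heterozygous carrier to wild-type mates, affected and
#' unaffected offspring are expected 1:1. Sums the counts over crosses and
#' tests the 1:1 expectation with an exact binomial test.
#'
#' @param affected,unaffected per-cross offspring counts (vectors).
#' @return List: `total`, `n_affected`, `n_unaffected`, `affected_fraction`,
#'   `binom_p` (two-sided exact test against 0.5).
#' @export
segregation_summary <- function(affected, unaffected) {
  na <- sum(affected); nu <- sum(unaffected)
  list(total = na + nu, n_affected = na, n_unaffected = nu,
       affected_fraction = na / (na + nu),
       binom_p = stats::binom.test(na, na + nu, 0.5)$p.value)
}
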