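# Shared fixtures built in code.

# straight horizontal ribbon mask: width_px rows high, len_px long
straight_ribbon_mask <- function(len_px = 400, width_px = 40, canvas_pad = 12,
                                 pixel_scale = 0.1) {
  nr <- width_px + 2 * canvas_pad
  nc <- len_px + 2 * canvas_pad
  m <- matrix(FALSE, nr, nc)
  m[canvas_pad + seq_len(width_px), canvas_pad + seq_len(len_px)] <- TRUE
  attr(m, "pixel_scale") <- pixel_scale
  m
}

# uniform-grid profile from a theta function of u
make_profile <- function(theta_fun, L = 100, n = 512) {
  u <- seq(0, 1, length.out = n)
  theta_profile(u, theta_fun(u), L)
}

# rendered edge polylines of a generated feather (jitter included)
truth_edges <- function(feather) feather$edges

# small Fig-3-style manual half-sib pedigree: sire het 1/2 at every marker
# (haplotype 1 carries the disease allele), dams homozygous 2/2, so the
# paternal allele of every offspring is directly readable
manual_halfsib <- function(n_off = 8, n_markers = 10,
                           pat_allele = matrix(1L, n_off, n_markers),
                           affected = rep(TRUE, n_off)) {
  ids <- c("S1", "D1", paste0("O", seq_len(n_off)))
  ind <- data.frame(id = ids,
                    father = c(NA, NA, rep("S1", n_off)),
                    mother = c(NA, NA, rep("D1", n_off)),
                    sex = c(1, 2, rep(2, n_off)),
                    affection = c(2, 1, ifelse(affected, 2, 1)))
  geno <- array(NA_integer_, c(length(ids), n_markers, 2))
  geno[1, , 1] <- 1L; geno[1, , 2] <- 2L
  geno[2, , 1] <- 2L; geno[2, , 2] <- 2L
  for (k in seq_len(n_off)) {
    geno[2 + k, , 1] <- pat_allele[k, ]
    geno[2 + k, , 2] <- 2L
  }
  pedigree(ind, geno)
}

# phase-known dominant backcross: grandparents fix the sire's phase, so n
# non-recombinant meioses give max LOD = n * log10(2)
phase_known_backcross <- function(n_off = 10, n_recomb = 0) {
  ids <- c("GF", "GM", "S", "D", paste0("K", seq_len(n_off)))
  ind <- data.frame(id = ids,
                    father = c(NA, NA, "GF", NA, rep("S", n_off)),
                    mother = c(NA, NA, "GM", NA, rep("D", n_off)),
                    sex = c(1, 2, 1, 2, rep(1, n_off)),
                    affection = c(2, 1, 2, 1, rep(2, n_off)))
  geno <- array(NA_integer_, c(length(ids), 1, 2))
  geno[1, 1, ] <- c(1, 1)    # affected grandsire homozygous 1: phase known
  geno[2, 1, ] <- c(2, 2)
  geno[3, 1, ] <- c(1, 2)
  geno[4, 1, ] <- c(2, 2)
  for (k in seq_len(n_off))   # affected child with paternal allele 2 = recombinant
    geno[4 + k, 1, ] <- if (k <= n_recomb) c(2, 2) else c(1, 2)
  pedigree(ind, geno)
}

# nearest-neighbour raster rotation about the image centre (background bg);
# output canvas sized to contain the rotated frame
rotate_image <- function(img, angle_deg, bg = 0.08) {
  th <- angle_deg * pi / 180
  nr <- nrow(img); nc <- ncol(img)
  nr2 <- ceiling(abs(nr * cos(th)) + abs(nc * sin(th))) + 4
  nc2 <- ceiling(abs(nc * cos(th)) + abs(nr * sin(th))) + 4
  rr <- matrix(seq_len(nr2), nr2, nc2)
  cc <- matrix(rep(seq_len(nc2), each = nr2), nr2, nc2)
  dr <- rr - (nr2 + 1) / 2; dc <- cc - (nc2 + 1) / 2
  sr <- round((nr + 1) / 2 + cos(th) * dr - sin(th) * dc)
  sc <- round((nc + 1) / 2 + sin(th) * dr + cos(th) * dc)
  out <- matrix(bg, nr2, nc2)
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out[cbind(rr[ok], cc[ok])] <- img[cbind(sr[ok], sc[ok])]
  out
}

# RMS difference modulo an additive constant and a small grid shift in u
# (up to `cells` grid cells), for invariance checks where resampling can
# move the arc-length origin by a pixel or two
rms_mod_shift <- function(p1, p2, cells = 2, trim = 0.05) {
  n <- length(p1$u)
  best <- Inf
  for (k in -cells:cells) {
    u2 <- p2$u + k / (n - 1)
    t2 <- approx(u2, p2$theta_deg, xout = p1$u, rule = 2)$y
    keep <- p1$u >= trim & p1$u <= 1 - trim
    d <- p1$theta_deg[keep] - t2[keep]
    best <- min(best, sqrt(mean((d - mean(d))^2)))
  }
  best
}
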