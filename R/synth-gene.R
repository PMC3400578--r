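#' Specify a synthetic gene
#'
#' Exon/intron layout, junction motifs and an optional planted cryptic donor
#' for the gene generator. The generated CDS is free of internal stop codons
#' and, in the exon that carries the cryptic site, free of any GT dinucleotide
#' other than the planted hexamer, so that the planted site is guaranteed to
#' be the unique best-scoring cryptic candidate in that exon.
#'
#' @param exon_lengths integer vector of exon lengths (nt, > 0).
#' @param intron_lengths integer vector of intron lengths; must have exactly
#'   `length(exon_lengths) - 1` elements, each at least
#'   `nchar(donor_motif) + 2`.
#' @param donor_motif nucleotide string placed at the start of every intron
#'   (must begin with GT); every intron ends with AG.
#' @param cryptic_site optional list `(exon, offset, hexamer)`: plant
#'   `hexamer` (must begin GT) in exon `exon` so that `offset` exonic nt lie
#'   from the hexamer start through the exon end. `offset` must be between 6
#'   and the exon length (a smaller offset would collide with the junction).
#' @param cds_start 1-based CDS start in spliced-mRNA coordinates. The CDS
#'   runs to the end of the mRNA and ends with a stop codon.
#' @param seed integer seed.
#' @return Object of class `gene_spec`.
#' @export
gene_spec <- function(exon_lengths, intron_lengths, donor_motif = "GTAAGT",
                      cryptic_site = NULL, cds_start = 1, seed = 1L) {
  fk_assert(length(intron_lengths) == length(exon_lengths) - 1, "InvalidSpec",
            "need exactly one fewer intron than exons")
  fk_assert(all(exon_lengths >= 1), "InvalidSpec", "exon lengths must be >= 1")
  fk_assert(startsWith(donor_motif, "GT") && grepl("^[ACGT]+$", donor_motif),
            "InvalidSpec", "donor_motif must start with GT and be over ACGT")
  fk_assert(all(intron_lengths >= nchar(donor_motif) + 2), "InvalidSpec",
            "introns must hold the donor motif plus the terminal AG")
  mrna_len <- sum(exon_lengths)
  fk_assert(cds_start >= 1 && cds_start < mrna_len &&
              (mrna_len - cds_start + 1) %% 3 == 0, "InvalidSpec",
            "CDS (cds_start to mRNA end) must be a positive multiple of 3")
  if (!is.null(cryptic_site)) {
    fk_assert(is.list(cryptic_site) &&
                all(c("exon", "offset", "hexamer") %in% names(cryptic_site)),
              "InvalidSpec", "cryptic_site needs fields exon, offset, hexamer")
    fk_assert(cryptic_site$exon >= 1 &&
                cryptic_site$exon <= length(exon_lengths), "InvalidSpec",
              "cryptic exon index out of range")
    fk_assert(startsWith(cryptic_site$hexamer, "GT") &&
                nchar(cryptic_site$hexamer) == 6, "InvalidSpec",
              "cryptic hexamer must be 6 nt starting GT")
    fk_assert(cryptic_site$offset < exon_lengths[cryptic_site$exon],
              "InvalidSpec", "cryptic offset must be smaller than the exon")
    fk_assert(cryptic_site$offset >= 6, "InvalidSpec",
              "cryptic hexamer at offset < 6 collides with the authentic junction")
  }
  structure(list(exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 donor_motif = donor_motif, cryptic_site = cryptic_site,
                 cds_start = as.integer(cds_start), seed = as.integer(seed)),
            class = "gene_spec")
}

# 61 sense codons
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

# replace every GT dinucleotide in x except those starting at `except`
# (1-based); T -> C never creates a new GT or a stop codon
scrub_gt <- function(x, except = integer()) {
  v <- strsplit(x, "")[[1]]
  repeat {
    hits <- which(v[-length(v)] == "G" & v[-1] == "T")
    hits <- setdiff(hits, except)
    if (!length(hits)) break
    v[hits + 1] <- "C"
  }
  paste(v, collapse = "")
}

#' Generate a synthetic gene with annotated structure
#'
#' Builds a genomic sequence from a [gene_spec()]: exons drawn as random
#' sense codons (terminal stop codon at the mRNA end), introns carrying the
#' donor motif at their start and AG at their end, and the cryptic hexamer
#' planted at the requested offset. In the cryptic exon all other GT
#' dinucleotides are scrubbed, so the planted hexamer is the unique
#' cryptic-donor candidate there.
#'
#' @param spec a [gene_spec()].
#' @return List with `model` (a [gene_model()]) and `spec`.
#' @export
generate_gene <- function(spec) {
  fk_assert(inherits(spec, "gene_spec"), "InvalidSpec",
            "spec must be a gene_spec")
  nex <- length(spec$exon_lengths)
  mrna_len <- sum(spec$exon_lengths)
  with_seed(child_seed(spec$seed, "gene"), {
    cod <- sense_codons()
    n_cod <- (mrna_len - spec$cds_start + 1) %/% 3
    mrna <- paste0(
      paste(sample(c("A", "C", "G", "T"), spec$cds_start - 1, replace = TRUE),
            collapse = ""),
      paste(sample(cod, n_cod - 1, replace = TRUE), collapse = ""), "TAA")
    ends <- cumsum(spec$exon_lengths)
    starts <- ends - spec$exon_lengths + 1
    exon_seq <- substring(mrna, starts, ends)
    if (!is.null(spec$cryptic_site)) {
      i <- spec$cryptic_site$exon
      p <- spec$exon_lengths[i] - spec$cryptic_site$offset + 1
      substr(exon_seq[i], p, p + 5) <- spec$cryptic_site$hexamer
      exon_seq[i] <- scrub_gt(exon_seq[i], except = p)
    }
    introns <- vapply(spec$intron_lengths, function(n) {
      mid <- scrub_gt(paste(sample(c("A", "C", "G", "T"),
                                   n - nchar(spec$donor_motif) - 2,
                                   replace = TRUE), collapse = ""))
      paste0(spec$donor_motif, mid, "AG")
    }, "")
    pieces <- character(2 * nex - 1)
    pieces[seq(1, 2 * nex - 1, by = 2)] <- exon_seq
    if (nex > 1) pieces[seq(2, 2 * nex - 2, by = 2)] <- introns
    genomic <- paste(pieces, collapse = "")
    glen <- nchar(exon_seq)
    gstart <- cumsum(c(1, head(glen, -1) + c(spec$intron_lengths, 0)[seq_len(nex - 1)]))
    exons <- data.frame(start = gstart, end = gstart + glen - 1)
    model <- gene_model("synthetic_gene", genomic, exons,
                        cds_start = spec$cds_start, cds_end = mrna_len,
                        donor_motif = spec$donor_motif)
    list(model = model, spec = spec)
  })
}

#' KRT75-like synthetic gene and deletion
#'
#' A synthetic gene mirroring the printed structure of the frizzle KRT75
#' allele: six exons with 802 coding nt upstream of a 200-nt fifth exon (so
#' the fifth exon ends at CDS position 1002), a GTGAAG cryptic donor planted
#' 69 nt upstream of the exon-5 donor junction, and an 84-bp deletion
#' spanning the last 25 exonic and first 59 intronic nt of that junction.
#' The codons at residues 311 and 334 are made identical, emulating the local
#' repeat in the real allele that left-shifts the reported protein deletion
#' to residues 311-333. The sequence itself is random (the true KRT75
#' sequence is not embedded); only the printed structural coordinates are
#' reproduced.
#'
#' @param seed integer seed.
#' @return List with `model` (a [gene_model()]), `variant` (the 84-bp
#'   [deletion_variant()] spanning the exon-5 donor), and `spec`.
#' @export
krt75_like_gene <- function(seed = 1L) {
  spec <- gene_spec(exon_lengths = c(250, 200, 180, 172, 200, 198),
                    intron_lengths = c(90, 90, 90, 90, 120),
                    donor_motif = "GTAAGT",
                    cryptic_site = list(exon = 5, offset = 69,
                                        hexamer = "GTGAAG"),
                    cds_start = 1, seed = seed)
  g <- generate_gene(spec)
  sq <- g$model$sequence
  ex5 <- g$model$exons[5, ]
  # plant identical codons at residues 311 and 334 (mRNA 931-933 / 1000-1002;
  # exon-5 local 129-131 / 198-200) and a distinct codon at residue 335
  loc <- function(k) ex5$start + k - 1
  for (off in c(129, 198)) substr(sq, loc(off), loc(off) + 2) <- "AAC"
  ex6 <- g$model$exons[6, ]
  substr(sq, ex6$start, ex6$start + 2) <- "GAT"
  # residues 310 and 333 get distinct amino acids so the protein alignment
  # stops exactly at the planted repeat
  substr(sq, loc(126), loc(128)) <- "GAA"
  substr(sq, loc(195), loc(197)) <- "CAT"
  model <- gene_model(g$model$seq_id, sq, g$model$exons,
                      cds_start = g$model$cds_start,
                      cds_end = g$model$cds_end,
                      donor_motif = g$model$donor_motif)
  variant <- deletion_variant(ex5$end - 24, ex5$end + 59)
  list(model = model, variant = variant, spec = spec)
}
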