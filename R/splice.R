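#' Gene model on a plus-strand genomic sequence
#'
#' Ordered exon intervals on a genomic sequence, with the CDS given in
#' spliced-mRNA coordinates. Introns are derived as the gaps between exons.
#' All coordinates are 1-based inclusive. Only plus-strand models are
#' supported.
#'
#' @param seq_id sequence identifier.
#' @param sequence genomic sequence (character, A/C/G/T).
#' @param exons data.frame or matrix with columns `start`, `end` (1-based
#'   inclusive, sorted, non-overlapping; introns must be >= 4 nt).
#' @param cds_start,cds_end CDS interval in spliced-mRNA coordinates.
#' @param strand only `"+"` is supported.
#' @param donor_motif annotated donor motif at the start of each intron
#'   (used as the scoring reference for cryptic candidates); default the
#'   first 6 nt of the first intron.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(seq_id, sequence, exons, cds_start, cds_end,
                       strand = "+", donor_motif = NULL) {
  if (!identical(strand, "+"))
    fk_stop("NotSupported", "only plus-strand gene models are supported")
  sequence <- toupper(as.character(sequence))
  fk_assert(grepl("^[ACGT]+$", sequence), "SchemaError",
            "sequence must be over {A,C,G,T}")
  exons <- as.data.frame(exons)
  fk_assert(all(c("start", "end") %in% names(exons)) && nrow(exons) >= 1,
            "SchemaError", "exons need columns start, end")
  exons <- exons[order(exons$start), c("start", "end")]
  fk_assert(all(exons$start <= exons$end), "SchemaError",
            "exon start must be <= end")
  fk_assert(exons$start[1] >= 1 && max(exons$end) <= nchar(sequence),
            "SchemaError", "exons out of sequence bounds")
  if (nrow(exons) > 1) {
    gaps <- exons$start[-1] - exons$end[-nrow(exons)] - 1
    fk_assert(all(gaps >= 4), "SchemaError",
              "exons overlap or introns are shorter than 4 nt")
  }
  mrna_len <- sum(exons$end - exons$start + 1)
  fk_assert(cds_start >= 1 && cds_end <= mrna_len && cds_start <= cds_end,
            "SchemaError", "CDS outside mRNA bounds")
  if (is.null(donor_motif) && nrow(exons) > 1)
    donor_motif <- substr(sequence, exons$end[1] + 1, exons$end[1] + 6)
  structure(list(seq_id = seq_id, sequence = sequence, exons = exons,
                 cds_start = cds_start, cds_end = cds_end, strand = "+",
                 donor_motif = donor_motif),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d nt genomic, %d exons, mRNA %d nt, CDS %d-%d\n",
              x$seq_id, nchar(x$sequence), nrow(x$exons),
              sum(x$exons$end - x$exons$start + 1), x$cds_start, x$cds_end))
  invisible(x)
}

#' Deletion variant on a genomic sequence
#'
#' 1-based inclusive interval; `deletion_variant()` with no arguments is the
#' empty (length-0) sentinel.
#'
#' @param start,end 1-based inclusive genomic coordinates, `start <= end`.
#' @return Object of class `deletion_variant`.
#' @examples
#' deletion_length(deletion_variant(658389, 658472))  # 84
#' @export
deletion_variant <- function(start = NULL, end = NULL) {
  if (is.null(start) && is.null(end))
    return(structure(list(start = NA_integer_, end = NA_integer_, empty = TRUE),
                     class = "deletion_variant"))
  fk_assert(is.numeric(start) && is.numeric(end) && start >= 1 && start <= end,
            "CoordinateError", "need 1 <= start <= end")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 empty = FALSE), class = "deletion_variant")
}

#' Parse a `seq_id:start-end` deletion string
#' @param x string like `"chrE22C19W28_E50C23:658389-658472"`.
#' @return A [deletion_variant()]; the seq_id is attached as an attribute.
#' @export
parse_variant <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4)
    fk_stop("ParseError", "cannot parse variant string '%s' (expected seq:start-end)", x)
  v <- deletion_variant(as.numeric(gsub(",", "", m[3])),
                        as.numeric(gsub(",", "", m[4])))
  attr(v, "seq_id") <- m[2]
  v
}

#' Length of a deletion in nucleotides
#' @param variant a [deletion_variant()].
#' @return `end - start + 1` (0 for the empty sentinel).
#' @export
deletion_length <- function(variant) {
  fk_assert(inherits(variant, "deletion_variant"), "CoordinateError",
            "variant must be a deletion_variant")
  if (variant$empty) return(0)
  variant$end - variant$start + 1
}

#' Excise a deletion from a sequence
#' @param sequence character sequence.
#' @param variant a [deletion_variant()]; must lie within the sequence.
#' @return The sequence with the interval removed.
#' @export
apply_deletion <- function(sequence, variant) {
  sequence <- as.character(sequence)
  if (variant$empty) return(sequence)
  n <- nchar(sequence)
  fk_assert(variant$start >= 1 && variant$end <= n, "CoordinateError",
            "deletion %d-%d out of bounds for a %d-nt sequence",
            variant$start, variant$end, n)
  paste0(substr(sequence, 1, variant$start - 1),
         substr(sequence, variant$end + 1, n))
}

# introns as a data.frame(start, end); zero rows for single-exon genes
model_introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2) return(data.frame(start = numeric(), end = numeric()))
  data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
}

# spliced mRNA of a (WT) model
spliced_mrna <- function(model) {
  paste(substring(model$sequence, model$exons$start, model$exons$end),
        collapse = "")
}

overlaps <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2

#' Classify splice-junction damage caused by a deletion
#'
#' A donor is lost when the deletion overlaps its junction motif (the last
#' exonic nt through the annotated donor motif at the intron start); an
#' acceptor is lost when the deletion overlaps the terminal AG of the intron
#' or the first exonic nt of the next exon. Exon truncation is reported for
#' every exon losing nucleotides.
#'
#' @param model a [gene_model()].
#' @param variant a [deletion_variant()].
#' @return List with `junctions` (data.frame: intron, donor, acceptor, each
#'   `"intact"` or `"lost"`) and `exons_truncated` (indices of exons losing
#'   nucleotides).
#' @export
classify_junction_damage <- function(model, variant) {
  ints <- model_introns(model)
  ex <- model$exons
  dlen <- max(2, nchar(model$donor_motif %||% "GT"))
  if (variant$empty) {
    return(list(junctions = data.frame(intron = seq_len(nrow(ints)),
                                       donor = "intact", acceptor = "intact"),
                exons_truncated = integer()))
  }
  donor <- acceptor <- character(nrow(ints))
  for (i in seq_len(nrow(ints))) {
    donor[i] <- if (overlaps(variant$start, variant$end,
                             ints$start[i] - 1, ints$start[i] + dlen - 1))
      "lost" else "intact"
    acceptor[i] <- if (overlaps(variant$start, variant$end,
                                ints$end[i] - 1, ints$end[i] + 1))
      "lost" else "intact"
  }
  trunc <- which(overlaps(variant$start, variant$end, ex$start, ex$end))
  list(junctions = data.frame(intron = seq_len(nrow(ints)),
                              donor = donor, acceptor = acceptor),
       exons_truncated = as.integer(trunc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hamming_score <- function(a, b) {
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Scan for cryptic donor candidates upstream of a lost donor
#'
#' Scans the exonic sequence of the damaged exon that survives the deletion
#' for hexamers beginning with GT, scores each by Hamming identity to the
#' authentic donor hexamer (the first 6 nt of the lost intron), and ranks by
#' score with ties broken by proximity to the lost junction.
#'
#' @param model a [gene_model()].
#' @param variant the [deletion_variant()] that destroyed the donor.
#' @param lost_intron index of the intron whose donor was lost; by default
#'   taken from [classify_junction_damage()] (error if none).
#' @param window_nt how far upstream of the junction to scan (default: the
#'   whole exon).
#' @return data.frame of class `donor_candidates`: `pos` (genomic position of
#'   the hexamer start), `hexamer`, `score` (matches out of 6), `offset_nt`
#'   (exonic nt from the hexamer start through the authentic junction, i.e.
#'   the mRNA length lost if this donor is used on the intact exon).
#' @export
find_cryptic_donor <- function(model, variant, lost_intron = NULL,
                               window_nt = NULL) {
  dmg <- classify_junction_damage(model, variant)
  lost <- which(dmg$junctions$donor == "lost")
  if (is.null(lost_intron)) {
    if (!length(lost))
      fk_stop("NoLostJunction", "no donor junction is lost by this deletion")
    lost_intron <- lost[1]
  } else if (!lost_intron %in% lost) {
    fk_stop("NoLostJunction", "donor of intron %d is not lost", lost_intron)
  }
  ex <- model$exons[lost_intron, ]
  ints <- model_introns(model)
  authentic <- substr(model$sequence, ints$start[lost_intron],
                      ints$start[lost_intron] + 5)
  # exonic positions surviving the deletion
  pos <- ex$start:ex$end
  if (!variant$empty) pos <- pos[pos < variant$start | pos > variant$end]
  if (!is.null(window_nt)) pos <- pos[pos > ex$end - window_nt]
  surv <- paste(substring(model$sequence, pos, pos), collapse = "")
  out <- data.frame(pos = numeric(), hexamer = character(), score = integer(),
                    offset_nt = numeric())
  if (nchar(surv) >= 6) {
    starts <- seq_len(nchar(surv) - 5)
    hex <- substring(surv, starts, starts + 5)
    gt <- startsWith(hex, "GT")
    if (any(gt)) {
      starts <- starts[gt]; hex <- hex[gt]
      out <- data.frame(pos = pos[starts], hexamer = hex,
                        score = vapply(hex, hamming_score, 0L, b = authentic),
                        offset_nt = ex$end - pos[starts] + 1)
      out <- out[order(-out$score, out$offset_nt), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "authentic") <- authentic
  attr(out, "lost_intron") <- lost_intron
  class(out) <- c("donor_candidates", "data.frame")
  out
}

translate_cds <- function(cds) {
  n <- (nchar(cds) %/% 3) * 3
  if (n == 0) return("")
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1, n)),
                          if.fuzzy.codon = "X")))
}

# left-aligned deletion interval between a (longer) and b: returns c(start,
# end) in a-coordinates, or NULL if a == b
align_deletion <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == nb && a == b) return(NULL)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  maxq <- min(na, nb)
  q <- 0
  while (q < maxq && av[na - q] == bv[nb - q]) q <- q + 1
  p <- 0
  while (p < maxq && av[p + 1] == bv[p + 1]) p <- p + 1
  qq <- min(q, nb)              # left-align: maximise the common suffix
  pp <- nb - qq
  if (pp > p) { pp <- p; qq <- nb - pp }
  c(pp + 1, na - qq)
}

#' Splice a mutant allele and derive its CDS/protein consequence
#'
#' Builds the mutant mRNA from a gene model and a deletion: exons surviving
#' the deletion are spliced with their authentic junctions, except that a
#' lost donor is replaced by the chosen cryptic candidate (the exon is
#' truncated immediately before the candidate's GT). With a lost donor and no
#' candidate, the downstream intron is retained. The CDS deletion interval is
#' reported in wild-type CDS coordinates as the nucleotides mechanically
#' removed (by the genomic deletion plus the cryptic truncation); the protein
#' deletion interval is derived by aligning the wild-type and mutant proteins
#' and is left-aligned when flanking residue repeats make the deletion
#' ambiguous (the convention used for the frizzle KRT75 residue numbering).
#'
#' @param model a [gene_model()].
#' @param variant a [deletion_variant()].
#' @param candidate a single row of [find_cryptic_donor()] output (or the
#'   whole ranking, in which case the top candidate is used); `NULL` for
#'   intact junctions or intron retention.
#' @return Object of class `splice_outcome`: mutant mRNA and protein, chosen
#'   candidate, `cds_deletion_interval` and length, `in_frame`,
#'   `protein_deletion_interval` and length, `frameshift`, `ptc_codon`
#'   (first premature stop codon index, NA if none), `intron_retained`.
#' @export
splice_mutant <- function(model, variant, candidate = NULL) {
  dmg <- classify_junction_damage(model, variant)
  lost <- which(dmg$junctions$donor == "lost")
  ex <- model$exons
  wt_mrna <- spliced_mrna(model)
  if (inherits(candidate, "donor_candidates")) {
    fk_assert(nrow(candidate) >= 1, "InvalidCandidate",
              "empty candidate ranking")
    candidate <- candidate[1, , drop = FALSE]
  }

  exon_pos <- function(i, upto = NULL) {
    p <- ex$start[i]:ex$end[i]
    if (!is.null(upto)) p <- p[p <= upto]
    p
  }
  del <- function(p) {
    if (variant$empty) p else p[p < variant$start | p > variant$end]
  }

  intron_retained <- FALSE
  if (length(lost)) {
    li <- lost[1]
    if (!is.null(candidate)) {
      fk_assert(candidate$pos >= ex$start[li] && candidate$pos <= ex$end[li],
                "InvalidCandidate",
                "candidate at %d is not within exon %d", candidate$pos, li)
      fk_assert(variant$empty || candidate$pos < variant$start,
                "InvalidCandidate",
                "candidate at %d is not upstream of the lost junction",
                candidate$pos)
      keep <- lapply(seq_len(nrow(ex)), function(i) {
        del(exon_pos(i, upto = if (i == li) candidate$pos - 1 else NULL))
      })
    } else {
      intron_retained <- TRUE
      keep <- lapply(seq_len(nrow(ex)), function(i) {
        p <- exon_pos(i)
        if (i == li) p <- c(p, (ex$end[li] + 1):(ex$start[li + 1] - 1))
        del(p)
      })
    }
  } else {
    keep <- lapply(seq_len(nrow(ex)), function(i) del(exon_pos(i)))
  }
  pos <- sort(unique(unlist(keep)))
  mut_mrna <- paste(substring(model$sequence, pos, pos), collapse = "")

  # mechanically removed WT mRNA positions
  wt_pos <- unlist(lapply(seq_len(nrow(ex)), exon_pos, upto = NULL))
  removed <- setdiff(wt_pos, pos)
  removed_mrna_idx <- which(wt_pos %in% removed)

  cds_del <- NULL; cds_len <- 0
  if (length(removed_mrna_idx)) {
    in_cds <- removed_mrna_idx[removed_mrna_idx >= model$cds_start &
                                 removed_mrna_idx <= model$cds_end]
    if (length(in_cds)) {
      cds_del <- c(min(in_cds), max(in_cds)) - model$cds_start + 1
      cds_len <- length(in_cds)
    }
  }
  # frame is preserved iff the net mRNA length change inside the CDS is a
  # multiple of 3; for pure deletions that is the deleted CDS length, for
  # intron retention it is the net change (retained intron minus deletion)
  in_frame <- if (intron_retained) {
    ((nchar(mut_mrna) - nchar(wt_mrna)) %% 3) == 0
  } else {
    (cds_len %% 3) == 0
  }

  wt_cds <- substr(wt_mrna, model$cds_start, model$cds_end)
  wt_prot <- translate_cds(wt_cds)
  wt_prot <- sub("\\*$", "", wt_prot)
  # mutant CDS: from cds_start to the end of the mutant mRNA (the 3' end moves
  # with the deletion/insertion); translation stops at the first stop codon
  mut_cds_full <- substr(mut_mrna, model$cds_start, nchar(mut_mrna))
  mut_prot_full <- translate_cds(mut_cds_full)
  stop_at <- regexpr("*", mut_prot_full, fixed = TRUE)
  mut_prot <- if (stop_at > 0) substr(mut_prot_full, 1, stop_at - 1)
    else mut_prot_full

  frameshift <- !in_frame
  ptc_codon <- NA_integer_
  if (frameshift && stop_at > 0 && stop_at <= nchar(wt_prot))
    ptc_codon <- as.integer(stop_at)

  prot_del <- NULL; prot_len <- 0
  if (in_frame && nchar(mut_prot) < nchar(wt_prot)) {
    iv <- align_deletion(wt_prot, mut_prot)
    if (!is.null(iv)) { prot_del <- iv; prot_len <- iv[2] - iv[1] + 1 }
  }

  structure(list(mutant_mrna = mut_mrna, mutant_protein = mut_prot,
                 candidate = candidate,
                 cds_deletion_interval = cds_del,
                 cds_deletion_length_nt = cds_len,
                 in_frame = in_frame,
                 protein_deletion_interval = prot_del,
                 protein_deletion_length_aa = prot_len,
                 frameshift = frameshift, ptc_codon = ptc_codon,
                 intron_retained = intron_retained),
            class = "splice_outcome")
}

#' @export
print.splice_outcome <- function(x, ...) {
  cat("<splice_outcome>\n")
  if (!is.null(x$cds_deletion_interval))
    cat(sprintf("  CDS deletion %d-%d (%d nt), %s\n",
                x$cds_deletion_interval[1], x$cds_deletion_interval[2],
                x$cds_deletion_length_nt,
                if (x$in_frame) "in frame" else "frameshift"))
  if (!is.null(x$protein_deletion_interval))
    cat(sprintf("  protein deletion %d-%d (%d aa)\n",
                x$protein_deletion_interval[1], x$protein_deletion_interval[2],
                x$protein_deletion_length_aa))
  if (x$intron_retained) cat("  intron retained\n")
  if (x$frameshift) cat(sprintf("  frameshift; PTC at codon %s\n",
                                as.character(x$ptc_codon)))
  invisible(x)
}

#' Diagnostic amplicon lengths across a deletion
#'
#' @param wt_amplicon either a stated wild-type length (single number; the
#'   deletion is then assumed to lie fully inside the amplicon) or a genomic
#'   interval `c(start, end)`.
#' @param variant a [deletion_variant()].
#' @param fwd_primer,rev_primer optional genomic intervals `c(start, end)`;
#'   if the deletion overlaps a primer site the result is flagged unreliable.
#' @return List `wt_len`, `mut_len`, `unreliable_primer`.
#' @examples
#' amplicon_lengths(851, deletion_variant(658389, 658472))  # 851 -> 767
#' @export
amplicon_lengths <- function(wt_amplicon, variant, fwd_primer = NULL,
                             rev_primer = NULL) {
  if (length(wt_amplicon) == 1) {
    wt_len <- wt_amplicon
    ov <- deletion_length(variant)
  } else {
    wt_len <- wt_amplicon[2] - wt_amplicon[1] + 1
    ov <- if (variant$empty) 0 else
      max(0, min(variant$end, wt_amplicon[2]) -
            max(variant$start, wt_amplicon[1]) + 1)
  }
  unreliable <- FALSE
  for (pr in list(fwd_primer, rev_primer)) {
    if (!is.null(pr) && !variant$empty &&
        overlaps(variant$start, variant$end, pr[1], pr[2]))
      unreliable <- TRUE
  }
  list(wt_len = wt_len, mut_len = wt_len - ov, unreliable_primer = unreliable)
}
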