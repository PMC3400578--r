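#' Haplotype sharing among affected offspring of a carrier sire
#'
#' Rule-based transmission inference for the half-sib mapping design (one
#' carrier sire, several wild-type dams, two generations). For every
#' offspring and marker, the paternally transmitted allele is inferred when
#' the maternal contribution is unambiguous (the allele left after removing
#' an allele the mother could have supplied); ambiguous transmissions stay
#' missing and are never imputed. Markers where the sire is not heterozygous,
#' or where no affected offspring has an inferred paternal allele, are
#' uninformative and bridged (they neither support nor break a run).
#'
#' The consensus carrier haplotype is the modal inferred paternal allele
#' among affected offspring per informative marker. Affected offspring with
#' mismatches are reported as recombinants, with the breakpoint bracketed by
#' the flanking informative markers; the shared interval is the maximal
#' contiguous run of informative markers over which all remaining affected
#' offspring carry the consensus allele.
#'
#' @param ped a [pedigree()] (two generations, single carrier sire).
#' @param markers marker ids or indices in map order (default: all, in
#'   stored order).
#' @param sire id of the carrier sire; by default the unique affected male
#'   founder with offspring.
#' @return Object of class `haplotype_share_report`: `shared_interval`
#'   (first/last marker id of the run), `shared_run` (marker ids),
#'   `consensus` (named allele vector over informative markers),
#'   `per_offspring` (data.frame id, n_informative, n_mismatch, consistent),
#'   `recombinants` (data.frame id, breakpoint_left, breakpoint_right),
#'   `uninformative_markers`.
#' @export
haplotype_share <- function(ped, markers = NULL, sire = NULL) {
  ind <- ped$ind
  if (is.null(markers)) markers <- seq_along(ped$markers)
  if (is.character(markers)) markers <- match(markers, ped$markers)
  mk_ids <- ped$markers[markers]

  if (is.null(sire)) {
    cand <- ind$id[is.na(ind$father) & ind$sex == 1 & ind$affection == 2 &
                     ind$id %in% ind$father[!is.na(ind$father)]]
    if (length(cand) != 1)
      fk_stop("InsufficientData",
              "cannot identify a unique carrier sire; pass `sire`")
    sire <- cand
  }
  si <- match(sire, ind$id)
  off <- which(!is.na(ind$father) & ind$father == sire)
  aff <- off[ind$affection[off] == 2]
  if (!length(aff)) fk_stop("InsufficientData", "no affected offspring")

  # inferred paternal allele: offspring allele whose partner the mother can
  # supply; unique solutions only
  infer_paternal <- function(child_g, mother_g) {
    if (any(is.na(child_g))) return(NA_integer_)
    cands <- integer()
    for (k in 1:2) {
      other <- child_g[3 - k]
      ok <- any(is.na(mother_g)) || other %in% mother_g
      if (ok) cands <- c(cands, child_g[k])
    }
    cands <- unique(cands)
    if (length(cands) == 1) cands else NA_integer_
  }

  pat <- matrix(NA_integer_, length(aff), length(markers),
                dimnames = list(ind$id[aff], mk_ids))
  for (a in seq_along(aff)) {
    mo <- match(ind$mother[aff[a]], ind$id)
    for (j in seq_along(markers)) {
      mj <- markers[j]
      mg <- if (is.na(mo)) c(NA, NA) else ped$geno[mo, mj, ]
      if (all(is.na(mg)))
        mg <- c(NA, NA)
      pat[a, j] <- infer_paternal(ped$geno[aff[a], mj, ], mg)
    }
  }

  sire_het <- vapply(markers, function(mj) {
    g <- ped$geno[si, mj, ]
    !any(is.na(g)) && g[1] != g[2]
  }, TRUE)
  informative <- sire_het & colSums(!is.na(pat)) > 0
  if (!any(informative))
    fk_stop("InsufficientData", "no informative marker")
  if (any(!informative))
    message(sprintf("haplotype_share: %d uninformative marker(s) bridged",
                    sum(!informative)))

  info_idx <- which(informative)
  consensus <- vapply(info_idx, function(j) {
    tab <- table(pat[, j])
    if (!length(tab)) return(NA_integer_)
    mx <- names(tab)[tab == max(tab)]
    if (length(mx) > 1) NA_integer_ else as.integer(mx)
  }, 1L)
  names(consensus) <- mk_ids[info_idx]

  match_mat <- matrix(NA, length(aff), length(info_idx))
  for (j in seq_along(info_idx))
    match_mat[, j] <- pat[, info_idx[j]] == consensus[j]

  n_mismatch <- rowSums(match_mat == FALSE, na.rm = TRUE)
  per_off <- data.frame(id = ind$id[aff],
                        n_informative = rowSums(!is.na(match_mat)),
                        n_mismatch = n_mismatch,
                        consistent = n_mismatch == 0)

  recomb <- lapply(which(n_mismatch > 0), function(a) {
    bad <- which(match_mat[a, ] == FALSE)
    good <- which(match_mat[a, ] == TRUE)
    left <- good[good < min(bad)]
    data.frame(id = ind$id[aff[a]],
               breakpoint_left = if (length(left))
                 mk_ids[info_idx[max(left)]] else NA_character_,
               breakpoint_right = mk_ids[info_idx[min(bad)]])
  })
  recombinants <- if (length(recomb)) do.call(rbind, recomb) else
    data.frame(id = character(), breakpoint_left = character(),
               breakpoint_right = character())

  # maximal contiguous informative-marker run where all non-recombinant
  # affected offspring match the consensus
  keep_rows <- which(n_mismatch == 0)
  col_ok <- vapply(seq_along(info_idx), function(j) {
    !is.na(consensus[j]) &&
      !any(match_mat[keep_rows, j] == FALSE, na.rm = TRUE)
  }, TRUE)
  r <- rle(col_ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  shared_run <- character()
  if (nrow(runs)) {
    best <- which.max(runs[, 2] - runs[, 1])
    shared_run <- mk_ids[info_idx[runs[best, 1]:runs[best, 2]]]
  }
  structure(list(
    shared_interval = if (length(shared_run))
      c(first = shared_run[1], last = shared_run[length(shared_run)]) else NULL,
    shared_run = shared_run,
    consensus = consensus,
    per_offspring = per_off,
    recombinants = recombinants,
    uninformative_markers = mk_ids[!informative]),
    class = "haplotype_share_report")
}

#' @export
print.haplotype_share_report <- function(x, ...) {
  cat(sprintf("<haplotype_share_report> shared run of %d markers (%s to %s); %d/%d offspring consistent, %d recombinant(s)\n",
              length(x$shared_run),
              x$shared_interval[1], x$shared_interval[2],
              sum(x$per_offspring$consistent), nrow(x$per_offspring),
              nrow(x$recombinants)))
  invisible(x)
}
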