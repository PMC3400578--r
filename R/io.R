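#' Read a grayscale image (PNG or TIFF)
#'
#' Multi-channel images are averaged to grayscale. Values are in \[0,1\],
#' rows are image rows from the top.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  fk_assert(file.exists(path), "ParseError", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                fk_stop("ParseError", "unsupported image format: .%s", ext))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  img
}

#' Write a grayscale image (PNG or TIFF, 8-bit)
#' @param image numeric matrix in \[0,1\].
#' @param path output path; format chosen from the extension.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path, bits.per.sample = 8),
         fk_stop("ParseError", "unsupported image format: .%s", ext))
  invisible(path)
}

#' Write / read a tangent-angle profile as CSV
#'
#' Columns `u`, `s_mm`, `theta_deg`; the total length is recoverable from
#' `s_mm`. Round trips are exact to printed precision (15 significant
#' digits).
#'
#' @param profile a [theta_profile()].
#' @param path CSV path.
#' @return `write_profile_csv` returns the path; `read_profile_csv` a
#'   [theta_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  fk_assert(inherits(profile, "theta_profile"), "InvalidSpec",
            "profile must be a theta_profile")
  df <- data.frame(u = sprintf("%.15g", profile$u),
                   s_mm = sprintf("%.15g", profile$u * profile$L_mm),
                   theta_deg = sprintf("%.15g", profile$theta_deg))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  fk_assert(file.exists(path), "ParseError", "file not found: %s", path)
  df <- read.table(path, sep = ",", header = TRUE)
  for (col in c("u", "s_mm", "theta_deg"))
    if (!col %in% names(df))
      fk_stop("ParseError", "profile CSV %s lacks column '%s'", path, col)
  L <- max(df$s_mm)
  theta_profile(df$u, df$theta_deg, L, meta = list(source = path))
}

#' Write kink calls as CSV
#' @param calls a `kink_calls` data.frame from [detect_kinks()].
#' @param path CSV path.
#' @export
write_kinks_csv <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings.
#'
#' @param path FASTA path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  fk_assert(file.exists(path), "ParseError", "file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write / read a gene model as JSON
#'
#' Documented schema: `seq_id`, `exons` (array of `{start, end}`),
#' `cds_start`, `cds_end`, `strand`, `donor_motif`, optionally `sequence`.
#' Reading validates the schema (sorted non-overlapping exons, CDS in
#' bounds) and raises `SchemaError` otherwise.
#'
#' @param model a [gene_model()].
#' @param path JSON path.
#' @param sequence_path optional FASTA path for the genomic sequence; if
#'   `NULL` the sequence is embedded in the JSON.
#' @export
write_gene_model_json <- function(model, path, sequence_path = NULL) {
  obj <- list(seq_id = model$seq_id, strand = model$strand,
              exons = model$exons, cds_start = model$cds_start,
              cds_end = model$cds_end, donor_motif = model$donor_motif)
  if (is.null(sequence_path)) {
    obj$sequence <- model$sequence
  } else {
    write_fasta(setNames(model$sequence, model$seq_id), sequence_path)
    obj$sequence_fasta <- basename(sequence_path)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gene_model_json
#' @param sequence genomic sequence, required if not embedded in the JSON.
#' @export
read_gene_model_json <- function(path, sequence = NULL) {
  fk_assert(file.exists(path), "ParseError", "file not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    fk_stop("ParseError", "bad JSON in %s: %s", path,
                            conditionMessage(e)))
  for (f in c("seq_id", "exons", "cds_start", "cds_end"))
    if (is.null(obj[[f]]))
      fk_stop("SchemaError", "gene-model JSON %s lacks field '%s'", path, f)
  sq <- obj$sequence %||% sequence
  if (is.null(sq))
    fk_stop("SchemaError", "no sequence embedded and none supplied")
  gene_model(obj$seq_id, sq, obj$exons, obj$cds_start, obj$cds_end,
             strand = obj$strand %||% "+",
             donor_motif = obj$donor_motif)
}

#' Import a gene model from a GFF3 subset
#'
#' Reads `exon` features of one gene from a GFF3 file (via rtracklayer) plus
#' the genomic sequence from FASTA. The CDS is assumed to start at the given
#' spliced-mRNA coordinate.
#'
#' @param gff_path GFF3 path (plus-strand exon features).
#' @param fasta_path FASTA with the genomic sequence.
#' @param cds_start,cds_end CDS interval in spliced-mRNA coordinates
#'   (default: whole mRNA).
#' @return A [gene_model()].
#' @export
read_gene_model_gff3 <- function(gff_path, fasta_path, cds_start = 1,
                                 cds_end = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_model_gff3 requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(gff_path))
  gr <- gr[gr$type == "exon", , drop = FALSE]
  fk_assert(nrow(gr) >= 1, "SchemaError", "no exon features in %s", gff_path)
  fk_assert(all(as.character(gr$strand) %in% c("+", "*")),
            "NotSupported", "only plus-strand models are supported")
  seqs <- read_fasta(fasta_path)
  seq_id <- as.character(gr$seqnames)[1]
  sq <- if (seq_id %in% names(seqs)) seqs[[seq_id]] else seqs[[1]]
  exons <- data.frame(start = gr$start, end = gr$end)
  if (is.null(cds_end)) cds_end <- sum(exons$end - exons$start + 1)
  gene_model(seq_id, sq, exons, cds_start, cds_end)
}

#' Write / read LINKAGE pre-makeped PED and MAP files
#'
#' PED: whitespace-separated, six fixed columns (family, id, father, mother,
#' sex, affection with 0 = unknown) followed by two allele columns per marker
#' (0 = missing). MAP: two columns, marker id and map order.
#'
#' @param ped a [pedigree()].
#' @param ped_path,map_path output paths.
#' @param famid family identifier (default "F1").
#' @export
write_ped_map <- function(ped, ped_path, map_path, famid = "F1") {
  ind <- ped$ind
  m <- dim(ped$geno)[2]
  g <- matrix(0L, nrow(ind), 2 * m)
  if (m) {
    g[, 2 * seq_len(m) - 1] <- ped$geno[, , 1]
    g[, 2 * seq_len(m)] <- ped$geno[, , 2]
    g[is.na(g)] <- 0L
  }
  aff <- ind$affection
  aff[is.na(aff)] <- 0L
  df <- cbind(data.frame(fam = famid, id = ind$id,
                         father = ifelse(is.na(ind$father), "0", ind$father),
                         mother = ifelse(is.na(ind$mother), "0", ind$mother),
                         sex = ind$sex, aff = aff),
              as.data.frame(g))
  write.table(df, ped_path, sep = " ", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  write.table(data.frame(marker = ped$markers, order = seq_len(m)),
              map_path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(ped_path)
}

#' @rdname write_ped_map
#' @return `read_ped_map` returns a [pedigree()].
#' @export
read_ped_map <- function(ped_path, map_path = NULL) {
  fk_assert(file.exists(ped_path), "ParseError", "file not found: %s", ped_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1)
    fk_stop("ParseError", "PED %s: inconsistent column counts (line %d has %d, line 1 has %d)",
            ped_path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  if (nf[1] < 6 || (nf[1] - 6) %% 2 != 0)
    fk_stop("ParseError", "PED %s: line 1 has %d columns; need 6 + 2 per marker",
            ped_path, nf[1])
  m <- (nf[1] - 6) / 2
  tab <- do.call(rbind, fields)
  aff <- as.integer(tab[, 6])
  aff[aff == 0] <- NA
  ind <- data.frame(id = tab[, 2], father = tab[, 3], mother = tab[, 4],
                    sex = as.integer(tab[, 5]), affection = aff)
  geno <- NULL
  if (m > 0) {
    geno <- matrix(as.integer(tab[, -(1:6), drop = FALSE]), nrow = nrow(tab))
    if (any(is.na(geno)))
      fk_stop("ParseError", "PED %s: non-integer allele code", ped_path)
  }
  markers <- NULL
  if (!is.null(map_path)) {
    fk_assert(file.exists(map_path), "ParseError", "file not found: %s",
              map_path)
    mp <- read.table(map_path, header = FALSE,
                     colClasses = c("character", "integer"))
    fk_assert(nrow(mp) == m, "ParseError",
              "MAP %s has %d markers but PED has %d", map_path, nrow(mp), m)
    markers <- mp[[1]][order(mp[[2]])]
  }
  pedigree(ind, geno, markers)
}

#' Write the feather generator's ground truth as a sidecar CSV
#' @param feather a `feather_image`.
#' @param path CSV path (columns u, s_mm, x_mm, y_mm, theta_deg).
#' @export
write_truth_csv <- function(feather, path) {
  fk_assert(inherits(feather, "feather_image"), "InvalidSpec",
            "feather must be a feather_image")
  write.table(feather$truth, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#' @param report a list of results (coerced with `auto_unbox`).
#' @param path JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
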