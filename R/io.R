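#' @title Readers and writers for the pipeline's tabular formats
#'
#' @description
#' All inputs and outputs are plain tab-separated text with a header row.
#' Protein groups mirror MaxQuant `proteinGroups.txt` column names where those
#' exist ("Razor + unique peptides", "Reporter intensity corrected <line>",
#' "Potential contaminant", "Reverse", "Only identified by site"); allele
#' counts follow the column set of standard allele-counting output (contig,
#' 1-based position, counts per allele); cytobands use UCSC `cytoBand.txt`
#' naming (e.g. "Xq23"). Readers validate schemas strictly and sort rows by
#' their declared keys so output is independent of input row order. Writers
#' emit a fixed column order with floats at 6 significant digits, so a
#' write-read-write cycle is byte-stable.
#'
#' @name io_formats
NULL

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), colClasses = "character")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    abort("%s: missing mandatory column(s): %s", what,
          paste(missing, collapse = ", "))
}

as_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) abort("%s: non-numeric value '%s'", what, x[bad][1])
  out
}

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA",
                ifelse(x == floor(x) & abs(x) < 1e15,
                       sprintf("%.0f", x), sprintf("%.6g", x)))
  out
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `line_id`, `donor_sex` (female/male),
#'   `tmt_plex`, `donor_id`.
#' @return a `data.frame` of class `xci_sample_sheet`, sorted by `line_id`
#'   order of appearance preserved in column `order` (plex assignment in the
#'   study is tied to acquisition order, so original order is kept).
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("line_id", "donor_sex", "tmt_plex", "donor_id"),
                  "sample sheet")
  if (anyDuplicated(df$line_id))
    abort("sample sheet: duplicate line_id '%s'",
          df$line_id[duplicated(df$line_id)][1])
  bad <- setdiff(unique(df$donor_sex), c("female", "male"))
  if (length(bad) > 0)
    abort("sample sheet: donor_sex must be 'female' or 'male', got '%s'", bad[1])
  out <- df[, c("line_id", "donor_sex", "tmt_plex", "donor_id")]
  class(out) <- c("xci_sample_sheet", "data.frame")
  out
}

new_sample_sheet <- function(line_id, donor_sex, tmt_plex, donor_id) {
  out <- data.frame(line_id = line_id, donor_sex = donor_sex,
                    tmt_plex = tmt_plex, donor_id = donor_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("xci_sample_sheet", "data.frame")
  out
}

#' Read an allele-count table of heterozygous SNP read counts
#'
#' Positions are 1-based and fully closed, matching conventional
#' allele-counting exports. `(contig, position, line_id)` must be unique.
#'
#' @param path TSV with columns `line_id`, `gene_id`, `contig`, `position`,
#'   `allele_a_count`, `allele_b_count`.
#' @return a `data.frame` of class `xci_allele_counts`, sorted by
#'   (line_id, contig, position).
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv_strict(path)
  cols <- c("line_id", "gene_id", "contig", "position",
            "allele_a_count", "allele_b_count")
  require_columns(df, cols, "allele counts")
  df <- df[, cols]
  df$position <- as_num(df$position, "allele counts: position")
  df$allele_a_count <- as_num(df$allele_a_count, "allele counts: allele_a_count")
  df$allele_b_count <- as_num(df$allele_b_count, "allele counts: allele_b_count")
  new_allele_counts(df)
}

new_allele_counts <- function(df) {
  if (any(is.na(df$position)) || any(df$position < 1) ||
      any(df$position != floor(df$position)))
    abort("allele counts: positions must be integers >= 1 (1-based)")
  if (any(df$allele_a_count < 0, na.rm = TRUE) ||
      any(df$allele_b_count < 0, na.rm = TRUE))
    abort("allele counts: read counts must be nonnegative")
  key <- paste(df$contig, df$position, df$line_id, sep = "\r")
  if (anyDuplicated(key))
    abort("allele counts: duplicate (contig, position, line_id) entry")
  df <- df[order(df$line_id, df$contig, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("xci_allele_counts", "data.frame")
  df
}

#' Read a gene-by-line expression matrix
#'
#' @param path TSV whose first column is `gene_id` and remaining columns are
#'   line identifiers; all values nonnegative.
#' @param layer one of `"rna_tpm"` or `"protein_copies"`; stored as an
#'   attribute and used downstream to pick the log transform.
#' @return numeric matrix (genes x lines) with attribute `layer`.
#' @export
read_expression_matrix <- function(path, layer = c("rna_tpm", "protein_copies")) {
  layer <- match.arg(layer)
  df <- read_tsv_strict(path)
  require_columns(df, "gene_id", "expression matrix")
  if (anyDuplicated(df$gene_id))
    abort("expression matrix: duplicate gene_id '%s'",
          df$gene_id[duplicated(df$gene_id)][1])
  lines <- setdiff(names(df), "gene_id")
  if (anyDuplicated(lines)) abort("expression matrix: duplicate line column")
  m <- vapply(lines, function(l) as_num(df[[l]], paste("column", l)),
              numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df), dimnames = list(df$gene_id, lines))
  new_expression_matrix(m, layer)
}

new_expression_matrix <- function(m, layer) {
  if (any(m < 0, na.rm = TRUE))
    abort("expression matrix: negative values are not allowed")
  m <- m[order(rownames(m)), , drop = FALSE]
  attr(m, "layer") <- layer
  m
}

#' Read a gene annotation table
#'
#' Maps genes to protein accessions, chromosomes and cytobands, and carries
#' functional set memberships used downstream (ribosomal subunits, ribosome
#' biogenesis, histone ruler anchors). The cytoband's chromosome prefix must
#' match the chromosome field; the histone set must be non-empty for any
#' proteomic-ruler run.
#'
#' @param path TSV with columns `gene_id`, `protein_accession` (empty for
#'   non-coding genes), `chromosome` (1-22, X, Y, MT), `cytoband`, and 0/1
#'   flags `ribosome_60S`, `ribosome_40S`, `ribosome_biogenesis`, `histone`.
#' @return a `data.frame` of class `xci_annotation`, sorted by `gene_id`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_strict(path)
  cols <- c("gene_id", "protein_accession", "chromosome", "cytoband",
            "ribosome_60S", "ribosome_40S", "ribosome_biogenesis", "histone")
  require_columns(df, cols, "annotation")
  df <- df[, cols]
  for (f in c("ribosome_60S", "ribosome_40S", "ribosome_biogenesis", "histone"))
    df[[f]] <- as_num(df[[f]], paste("annotation:", f)) != 0
  new_annotation(df)
}

new_annotation <- function(df) {
  bad <- setdiff(unique(df$chromosome), VALID_CHROMOSOMES)
  if (length(bad) > 0)
    abort("annotation: unknown chromosome label '%s'", bad[1])
  if (anyDuplicated(df$gene_id))
    abort("annotation: duplicate gene_id '%s'",
          df$gene_id[duplicated(df$gene_id)][1])
  has_band <- !is.na(df$cytoband) & df$cytoband != ""
  prefix <- sub("^([0-9]+|X|Y|MT)[pq].*$", "\\1", df$cytoband[has_band])
  mism <- prefix != df$chromosome[has_band]
  if (any(mism))
    abort("annotation: cytoband '%s' does not match chromosome '%s'",
          df$cytoband[has_band][mism][1], df$chromosome[has_band][mism][1])
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("xci_annotation", "data.frame")
  df
}

#' Read a MaxQuant-style protein-group table
#'
#' Expects the `proteinGroups.txt` column dialect: "Protein IDs" (semicolon
#' separated accessions), "Gene names", "Mol. weight [kDa]",
#' "Razor + unique peptides", QC flags marked with "+", and one
#' "Reporter intensity corrected `<line_id>`" column per sample-sheet line.
#' Missing intensities are kept missing (`NA`), never coerced to zero:
#' zeros would enter proteomic-ruler sums, missing values must not.
#'
#' @param path TSV path.
#' @param sample_sheet an `xci_sample_sheet`; defines which reporter columns
#'   are mandatory.
#' @return an object of class `xci_protein_groups`: list with `info`
#'   (data.frame: `accessions`, `gene_name`, `mw_da`, `razor_unique_peptides`,
#'   `is_contaminant`, `is_reverse`, `is_only_site`) and `intensity`
#'   (matrix protein-group x line, rownames = full accession strings).
#' @export
read_protein_groups <- function(path, sample_sheet) {
  df <- read_tsv_strict(path)
  base_cols <- c("Protein IDs", "Gene names", "Mol. weight [kDa]",
                 "Razor + unique peptides", "Potential contaminant",
                 "Reverse", "Only identified by site")
  require_columns(df, base_cols, "protein groups")
  rep_cols <- paste("Reporter intensity corrected", sample_sheet$line_id)
  require_columns(df, rep_cols, "protein groups")
  if (anyDuplicated(df[["Protein IDs"]]))
    abort("protein groups: duplicate accession row '%s'",
          df[["Protein IDs"]][duplicated(df[["Protein IDs"]])][1])
  n <- nrow(df)
  info <- data.frame(
    accessions = as.character(df[["Protein IDs"]]),
    gene_name = ifelse(is.na(df[["Gene names"]]), "", df[["Gene names"]]),
    mw_da = as_num(df[["Mol. weight [kDa]"]], "Mol. weight [kDa]") * 1000,
    razor_unique_peptides = as_num(df[["Razor + unique peptides"]],
                                   "Razor + unique peptides"),
    is_contaminant = !is.na(df[["Potential contaminant"]]) &
      df[["Potential contaminant"]] == "+",
    is_reverse = !is.na(df[["Reverse"]]) & df[["Reverse"]] == "+",
    is_only_site = !is.na(df[["Only identified by site"]]) &
      df[["Only identified by site"]] == "+",
    stringsAsFactors = FALSE)
  intensity <- matrix(NA_real_, nrow = n, ncol = length(rep_cols),
                      dimnames = list(info$accessions, sample_sheet$line_id))
  for (i in seq_along(rep_cols))
    intensity[, i] <- as_num(df[[rep_cols[i]]], rep_cols[i])
  new_protein_groups(info, intensity)
}

new_protein_groups <- function(info, intensity) {
  if (nrow(info) > 0) {
    if (any(is.na(info$mw_da)) || any(info$mw_da <= 0))
      abort("protein groups: molecular weights must be positive")
    if (any(info$razor_unique_peptides < 0, na.rm = TRUE))
      abort("protein groups: peptide counts must be nonnegative")
    if (any(intensity < 0, na.rm = TRUE))
      abort("protein groups: reporter intensities must be nonnegative or missing")
  }
  stopifnot(nrow(info) == nrow(intensity))
  structure(list(info = info, intensity = intensity),
            class = "xci_protein_groups")
}

#' Primary accession of each protein group (first token of "Protein IDs")
#' @param pg an `xci_protein_groups` object.
#' @return character vector.
#' @export
primary_accession <- function(pg) {
  vapply(strsplit(pg$info$accessions, ";", fixed = TRUE), `[`, "", 1)
}

#' @export
print.xci_protein_groups <- function(x, ...) {
  cat(sprintf("Protein group table: %d groups x %d lines\n",
              nrow(x$info), ncol(x$intensity)))
  invisible(x)
}

#' Write any pipeline table as deterministic TSV
#'
#' Dispatches on the table class. Column order is fixed and floats use 6
#' significant digits, so identical inputs always give byte-identical files.
#'
#' @param x a table produced by this package (sample sheet, allele counts,
#'   expression matrix, annotation, or protein groups).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_table <- function(x, path) UseMethod("write_table")

write_df_tsv <- function(df, path, numeric_cols) {
  cells <- lapply(names(df), function(cn) {
    v <- df[[cn]]
    if (cn %in% numeric_cols) fmt_num(v)
    else ifelse(is.na(v), "NA", as.character(v))
  })
  body <- do.call(paste, c(cells, sep = "\t"))
  write_lines_lf(c(paste(names(df), collapse = "\t"), body), path)
}

#' @export
write_table.xci_sample_sheet <- function(x, path) {
  write_df_tsv(x[, c("line_id", "donor_sex", "tmt_plex", "donor_id")], path,
               character(0))
}

#' @export
write_table.xci_allele_counts <- function(x, path) {
  write_df_tsv(x[, c("line_id", "gene_id", "contig", "position",
                     "allele_a_count", "allele_b_count")], path,
               c("position", "allele_a_count", "allele_b_count"))
}

#' @export
write_table.xci_annotation <- function(x, path) {
  df <- x
  for (f in c("ribosome_60S", "ribosome_40S", "ribosome_biogenesis", "histone"))
    df[[f]] <- as.integer(df[[f]])
  write_df_tsv(df, path, c("ribosome_60S", "ribosome_40S",
                           "ribosome_biogenesis", "histone"))
}

#' @export
write_table.matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  for (l in colnames(x)) df[[l]] <- x[, l]
  write_df_tsv(df, path, colnames(x))
}

#' @export
write_table.xci_protein_groups <- function(x, path) {
  flag <- function(b) ifelse(b, "+", "")
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = x$info$accessions,
    `Gene names` = x$info$gene_name,
    `Mol. weight [kDa]` = fmt_num(x$info$mw_da / 1000),
    `Razor + unique peptides` = fmt_num(x$info$razor_unique_peptides),
    `Potential contaminant` = flag(x$info$is_contaminant),
    `Reverse` = flag(x$info$is_reverse),
    `Only identified by site` = flag(x$info$is_only_site))
  for (l in colnames(x$intensity)) {
    v <- x$intensity[, l]
    df[[paste("Reporter intensity corrected", l)]] <-
      ifelse(is.na(v), "", fmt_num(v))
  }
  body <- do.call(paste, c(df, sep = "\t"))
  write_lines_lf(c(paste(names(df), collapse = "\t"), body), path)
}
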