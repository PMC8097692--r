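#' Proteomic ruler configuration
#'
#' The histone proteomic ruler converts reporter intensities to absolute
#' copies per cell by anchoring the total histone signal of each line to the
#' DNA mass of a diploid human cell.
#'
#' @param dna_mass_per_cell_pg DNA mass per cell in picograms (default 6.5,
#'   diploid human genome).
#' @param min_rup minimum "Razor + unique peptides" for a protein group to
#'   be quantified (default 3).
#' @return an `xci_ruler_config` list.
#' @export
ruler_config <- function(dna_mass_per_cell_pg = 6.5, min_rup = 3) {
  if (dna_mass_per_cell_pg <= 0)
    abort("ruler config: dna_mass_per_cell_pg must be > 0")
  if (min_rup < 1) abort("ruler config: min_rup must be >= 1")
  structure(list(dna_mass_per_cell_pg = dna_mass_per_cell_pg,
                 min_rup = min_rup, avogadro = AVOGADRO),
            class = "xci_ruler_config")
}

#' Filter protein groups on QC flags and peptide support
#'
#' Removes contaminants, reverse hits and "only identified by site" rows,
#' then rows with fewer than `min_rup` razor + unique peptides. Row order is
#' preserved.
#'
#' @param pg an `xci_protein_groups` object.
#' @param config an [ruler_config()].
#' @return filtered `xci_protein_groups`.
#' @export
filter_protein_groups <- function(pg, config = ruler_config()) {
  info <- pg$info
  keep <- !(info$is_contaminant | info$is_reverse | info$is_only_site)
  keep <- keep & info$razor_unique_peptides >= config$min_rup
  new_protein_groups(info[keep, , drop = FALSE],
                     pg$intensity[keep, , drop = FALSE])
}

histone_rows <- function(pg, annotation) {
  hist_acc <- annotation$protein_accession[annotation$histone]
  hist_acc <- hist_acc[!is.na(hist_acc)]
  if (length(hist_acc) == 0)
    abort("proteomic ruler: the annotation defines no histone proteins")
  acc_lists <- strsplit(pg$info$accessions, ";", fixed = TRUE)
  rows <- which(vapply(acc_lists, function(a) any(a %in% hist_acc), TRUE))
  if (length(rows) == 0)
    abort("proteomic ruler: no histone protein group found in the table")
  rows
}

#' Absolute copy numbers per cell via the histone proteomic ruler
#'
#' Per line j and protein i:
#' `copies(i, j) = I(i, j) * m_DNA * N_A / (MW_i * sum_histones I(h, j))`
#' with `m_DNA` the configured DNA mass per cell in grams and `N_A`
#' Avogadro's number. Copies are invariant to any per-line rescaling of all
#' intensities, and the summed histone mass per line equals `m_DNA` exactly.
#' Missing intensities stay missing.
#'
#' @param pg a filtered `xci_protein_groups`.
#' @param annotation an `xci_annotation` whose histone set identifies the
#'   anchor protein groups.
#' @param config an [ruler_config()].
#' @return copy-number matrix (proteins x lines), rownames = primary
#'   accessions, with attribute `mw_da` aligned to rows.
#' @export
ruler_copy_numbers <- function(pg, annotation, config = ruler_config()) {
  hr <- histone_rows(pg, annotation)
  hist_sum <- colSums(pg$intensity[hr, , drop = FALSE], na.rm = TRUE)
  n_obs <- colSums(!is.na(pg$intensity[hr, , drop = FALSE]))
  bad <- hist_sum <= 0 | n_obs == 0
  if (any(bad))
    abort("proteomic ruler: line '%s' has no histone signal",
          colnames(pg$intensity)[bad][1])
  dna_g <- config$dna_mass_per_cell_pg * 1e-12
  copies <- sweep(pg$intensity, 2, hist_sum, `/`) *
    (dna_g * config$avogadro) / pg$info$mw_da
  rownames(copies) <- primary_accession(pg)
  attr(copies, "mw_da") <- stats::setNames(pg$info$mw_da, rownames(copies))
  copies
}

#' Per-line protein content in picograms
#'
#' `content(j) = sum_i copies(i, j) * MW_i / N_A * 1e12`, skipping missing
#' values.
#'
#' @param copies copy-number matrix with rownames.
#' @param mw_da molecular weights (Da) named by accession, or `NULL` to use
#'   the `mw_da` attribute attached by [ruler_copy_numbers()].
#' @return named numeric vector, one value per line.
#' @export
protein_content_pg <- function(copies, mw_da = NULL) {
  if (is.null(mw_da)) mw_da <- attr(copies, "mw_da")
  if (is.null(mw_da)) abort("protein_content_pg: molecular weights required")
  mw <- mw_da[rownames(copies)]
  if (anyNA(mw))
    abort("protein_content_pg: missing molecular weight for '%s'",
          rownames(copies)[is.na(mw)][1])
  colSums(copies * mw, na.rm = TRUE) / AVOGADRO * 1e12
}

#' Correct TMT plex batch effects on copy numbers
#'
#' Multiplicative per-plex equalization of the median per-line protein mass:
#' each plex's copies are scaled by (grand median of per-line total protein
#' mass) / (median over that plex's lines). Within-plex ratios between any
#' two proteins are preserved exactly and the correction is idempotent.
#'
#' @param copies copy-number matrix from [ruler_copy_numbers()].
#' @param sample_sheet an `xci_sample_sheet` assigning every line to a plex.
#' @param mw_da optional molecular weights (defaults to the matrix
#'   attribute).
#' @return corrected matrix with attribute `plex_factors` (named vector of
#'   applied factors); `mw_da` attribute is carried over.
#' @export
batch_correct <- function(copies, sample_sheet, mw_da = NULL) {
  if (is.null(mw_da)) mw_da <- attr(copies, "mw_da")
  mass <- protein_content_pg(copies, mw_da)
  if (any(mass <= 0))
    abort("batch_correct: line '%s' has zero protein mass",
          names(mass)[mass <= 0][1])
  plex <- sample_sheet$tmt_plex[match(colnames(copies),
                                      sample_sheet$line_id)]
  if (anyNA(plex))
    abort("batch_correct: line '%s' missing from the sample sheet",
          colnames(copies)[is.na(plex)][1])
  grand <- stats::median(mass)
  plex_median <- tapply(mass, plex, stats::median)
  factors <- stats::setNames(as.numeric(grand / plex_median),
                             names(plex_median))
  out <- sweep(copies, 2, factors[plex], `*`)
  attr(out, "mw_da") <- mw_da
  attr(out, "plex_factors") <- factors[sort(names(factors))]
  out
}

#' Ratio of summed copy numbers between two protein sets (e.g. 60S/40S)
#'
#' Per line, the sum of copies over set A divided by the sum over set B;
#' by default the large (60S) over the small (40S) cytoplasmic ribosomal
#' subunit, a translation-machinery stoichiometry readout.
#'
#' @param copies copy-number matrix (rownames = accessions).
#' @param annotation an `xci_annotation`.
#' @param set_a,set_b names of annotation flag columns (defaults
#'   `"ribosome_60S"` and `"ribosome_40S"`).
#' @return named numeric vector per line; `NA` (with a warning) where the
#'   denominator sum is zero.
#' @export
subunit_ratio <- function(copies, annotation,
                          set_a = "ribosome_60S", set_b = "ribosome_40S") {
  acc_of <- function(flag) {
    a <- annotation$protein_accession[annotation[[flag]]]
    a <- a[!is.na(a)]
    if (length(a) == 0) abort("subunit_ratio: set '%s' is empty", flag)
    intersect(rownames(copies), a)
  }
  num <- colSums(copies[acc_of(set_a), , drop = FALSE], na.rm = TRUE)
  den <- colSums(copies[acc_of(set_b), , drop = FALSE], na.rm = TRUE)
  zero <- den == 0
  if (any(zero))
    warning(sprintf("subunit_ratio: zero denominator for line(s) %s",
                    paste(names(den)[zero], collapse = ", ")), call. = FALSE)
  out <- num / den
  out[zero] <- NA_real_
  out
}

#' Compare per-line protein content between groups
#'
#' For each group pair: percent difference of medians,
#' `100 * (median_A - median_B) / median_B`, and a Welch two-sample t test
#' on the per-line contents.
#'
#' @param content named per-line vector (e.g. from [protein_content_pg()]).
#' @param groups named list of character vectors of line ids.
#' @return data.frame: `group_a`, `group_b`, `median_a`, `median_b`,
#'   `pct_difference`, `t_stat`, `df`, `p_value`.
#' @export
group_content_summary <- function(content, groups) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  vals <- lapply(groups, function(ids) {
    missing <- setdiff(ids, names(content))
    if (length(missing) > 0)
      abort("group_content_summary: no content for line '%s'", missing[1])
    content[ids]
  })
  sizes <- vapply(vals, length, 0L)
  if (any(sizes < 2))
    abort("group_content_summary: group '%s' has fewer than 2 lines",
          names(groups)[sizes < 2][1])
  pairs <- utils::combn(names(groups), 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ma <- stats::median(vals[[a]]); mb <- stats::median(vals[[b]])
    tt <- stats::t.test(vals[[a]], vals[[b]], var.equal = FALSE)
    data.frame(group_a = a, group_b = b, median_a = ma, median_b = mb,
               pct_difference = 100 * (ma - mb) / mb,
               t_stat = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
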