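#' Stratification configuration
#'
#' Female lines are classified by XIST expression on the log2(TPM +
#' pseudocount) scale: below `low_threshold_log2tpm` is Low, above
#' `high_threshold_log2tpm` is High, otherwise Medium (strict inequalities,
#' so boundary values fall to Medium). `max_lines_per_plex` caps how many
#' High-XIST lines a single TMT plex may contribute after filtering.
#'
#' @param low_threshold_log2tpm default 1.0.
#' @param high_threshold_log2tpm default 2.75.
#' @param max_lines_per_plex default 4.
#' @param log2_pseudocount pseudocount for zero TPM, default 0.01.
#' @return an `xci_stratify_config` list.
#' @export
stratify_config <- function(low_threshold_log2tpm = 1.0,
                            high_threshold_log2tpm = 2.75,
                            max_lines_per_plex = 4,
                            log2_pseudocount = 0.01) {
  if (low_threshold_log2tpm >= high_threshold_log2tpm)
    abort("stratify config: low threshold must be below high threshold")
  if (max_lines_per_plex < 1)
    abort("stratify config: max_lines_per_plex must be >= 1")
  structure(list(low_threshold_log2tpm = low_threshold_log2tpm,
                 high_threshold_log2tpm = high_threshold_log2tpm,
                 max_lines_per_plex = max_lines_per_plex,
                 log2_pseudocount = log2_pseudocount),
            class = "xci_stratify_config")
}

#' Stratify female lines by XIST RNA expression
#'
#' @param rna expression matrix (layer `rna_tpm`) containing an XIST row.
#' @param sample_sheet an `xci_sample_sheet`; male lines are excluded from
#'   strata.
#' @param config an [stratify_config()].
#' @param xist_gene row name of the XIST gene (default `"XIST"`).
#' @return data.frame of class `xci_strata`: `line_id`, `log2_xist`,
#'   `stratum` (Low/Medium/High), one row per female line.
#' @export
stratify_by_xist <- function(rna, sample_sheet, config = stratify_config(),
                             xist_gene = "XIST") {
  if (!xist_gene %in% rownames(rna))
    abort("stratify_by_xist: gene '%s' not present in the expression matrix",
          xist_gene)
  females <- sample_sheet$line_id[sample_sheet$donor_sex == "female"]
  missing <- setdiff(females, colnames(rna))
  if (length(missing) > 0)
    abort("stratify_by_xist: female line '%s' missing from the matrix",
          missing[1])
  v <- log2(rna[xist_gene, females] + config$log2_pseudocount)
  stratum <- ifelse(v < config$low_threshold_log2tpm, "Low",
                    ifelse(v > config$high_threshold_log2tpm, "High",
                           "Medium"))
  out <- data.frame(line_id = females, log2_xist = unname(v),
                    stratum = unname(stratum), stringsAsFactors = FALSE)
  class(out) <- c("xci_strata", "data.frame")
  out
}

#' Stratum counts and percentages
#'
#' Percentages are rounded half-up to one decimal, the convention used for
#' all reported proportions.
#'
#' @param strata an `xci_strata` table.
#' @return data.frame: `stratum`, `n`, `pct`.
#' @export
stratum_percentages <- function(strata) {
  lev <- c("Low", "Medium", "High")
  n <- vapply(lev, function(s) sum(strata$stratum == s), 0L)
  data.frame(stratum = lev, n = as.integer(n),
             pct = round_half_up(100 * n / nrow(strata), 1),
             stringsAsFactors = FALSE)
}

#' Cap the number of High-XIST lines contributed per TMT plex
#'
#' Plexes contributing more than `max_lines_per_plex` High lines are reduced
#' by average-linkage hierarchical clustering on 1 - Pearson correlation of
#' log10 protein copy profiles, cut at k = `max_lines_per_plex`; the medoid
#' of each cluster (smallest summed distance to its cluster, lexicographic
#' line-id tie-break) is retained. Plexes at or under the cap are untouched.
#' Lines without protein data are dropped with a warning.
#'
#' @param high_lines character vector of High-XIST line ids.
#' @param copies copy-number matrix (proteins x lines).
#' @param sample_sheet an `xci_sample_sheet`.
#' @param config an [stratify_config()].
#' @return sorted character vector of retained line ids.
#' @export
cap_plex_replicates <- function(high_lines, copies, sample_sheet,
                                config = stratify_config()) {
  no_data <- setdiff(high_lines, colnames(copies))
  if (length(no_data) > 0) {
    warning(sprintf("dropping %d High-XIST line(s) without protein data: %s",
                    length(no_data), paste(no_data, collapse = ", ")),
            call. = FALSE)
    high_lines <- setdiff(high_lines, no_data)
  }
  plex <- sample_sheet$tmt_plex[match(high_lines, sample_sheet$line_id)]
  if (anyNA(plex))
    abort("cap_plex_replicates: line '%s' missing from the sample sheet",
          high_lines[is.na(plex)][1])
  retained <- character(0)
  for (p in unique(plex)) {
    lines_p <- sort(high_lines[plex == p])
    if (length(lines_p) <= config$max_lines_per_plex) {
      retained <- c(retained, lines_p)
      next
    }
    lc <- log10(copies[, lines_p, drop = FALSE])
    lc[!is.finite(lc)] <- NA
    cc <- suppressWarnings(stats::cor(lc, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 1  # constant/identical profiles: distance 0
    d <- stats::as.dist(1 - cc)
    cl <- stats::cutree(stats::hclust(d, method = "average"),
                        k = config$max_lines_per_plex)
    dm <- as.matrix(d)
    for (k in sort(unique(cl))) {
      members <- lines_p[cl == k]
      tot <- colSums(dm[members, members, drop = FALSE])
      medoid <- members[order(tot, members)][1]
      retained <- c(retained, medoid)
    }
  }
  sort(retained)
}
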