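#' Percentages of significant genes, rounded as reported
#'
#' `100 * n / n_total`, rounded half-up to one decimal — the rounding
#' convention of all reported proportions.
#'
#' @param n count(s) of significant genes.
#' @param n_total total gene count (> 0).
#' @return numeric vector of percentages.
#' @export
de_percentages <- function(n, n_total) {
  if (any(n_total == 0)) abort("de_percentages: n_total must be > 0")
  if (any(n > n_total)) abort("de_percentages: n exceeds n_total")
  round_half_up(100 * n / n_total, 1)
}

#' Chromosome-level summary of RNA and protein fold changes
#'
#' Restricted to genes present (with a fold change) in both layers. Per
#' chromosome and layer: median and SEM (sample SD / sqrt(n)) of the
#' per-gene log2 fold changes, significant up/down counts and percentages
#' at the q threshold; plus the Pearson correlation between the RNA and
#' protein fold-change vectors over that chromosome's shared genes
#' (`NA` when fewer than 3 shared genes).
#'
#' @param de_rna,de_protein `xci_de` tables. Protein tables are keyed by
#'   accession; `annotation` maps them back to genes.
#' @param annotation an `xci_annotation`.
#' @param q_threshold significance threshold (default 0.05).
#' @return data.frame: `chromosome`, `layer`, `n_genes`, `median_log2_fc`,
#'   `sem`, `n_up`, `n_down`, `pct_up`, `pct_down`,
#'   `pearson_r_rna_vs_protein_fc`.
#' @export
summarize_by_chromosome <- function(de_rna, de_protein, annotation,
                                    q_threshold = 0.05) {
  prot_gene <- annotation$gene_id[match(de_protein$gene_id,
                                        annotation$protein_accession)]
  dp <- de_protein
  dp$gene_id <- ifelse(is.na(prot_gene), de_protein$gene_id, prot_gene)
  shared <- intersect(de_rna$gene_id[!is.na(de_rna$log2_fc)],
                      dp$gene_id[!is.na(dp$log2_fc)])
  ir <- match(shared, de_rna$gene_id)
  ip <- match(shared, dp$gene_id)
  chr <- annotation$chromosome[match(shared, annotation$gene_id)]
  if (anyNA(chr))
    abort("summarize_by_chromosome: gene '%s' missing from annotation",
          shared[is.na(chr)][1])
  one_layer <- function(de, idx, layer, ch) {
    fc <- de$log2_fc[idx]
    q <- de$q_value[idx]
    per_chr <- lapply(unique(ch), function(cc) {
      sel <- ch == cc
      n <- sum(sel)
      n_up <- sum(q[sel] <= q_threshold & fc[sel] > 0, na.rm = TRUE)
      n_down <- sum(q[sel] <= q_threshold & fc[sel] < 0, na.rm = TRUE)
      data.frame(chromosome = cc, layer = layer, n_genes = n,
                 median_log2_fc = stats::median(fc[sel]),
                 sem = stats::sd(fc[sel]) / sqrt(n),
                 n_up = n_up, n_down = n_down,
                 pct_up = de_percentages(n_up, n),
                 pct_down = de_percentages(n_down, n),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_chr)
  }
  out <- rbind(one_layer(de_rna, ir, "rna", chr),
               one_layer(dp, ip, "protein", chr))
  r_by_chr <- vapply(unique(chr), function(cc) {
    sel <- chr == cc
    if (sum(sel) < 3) return(NA_real_)
    suppressWarnings(stats::cor(de_rna$log2_fc[ir][sel],
                                dp$log2_fc[ip][sel]))
  }, 0)
  out$pearson_r_rna_vs_protein_fc <- r_by_chr[out$chromosome]
  ord <- match(out$chromosome, VALID_CHROMOSOMES)
  out <- out[order(out$layer, ord), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median of a per-gene metric over cytobands
#'
#' @param gene_metric data.frame with columns `gene_id` and `value`.
#' @param annotation an `xci_annotation`; genes without a band are excluded
#'   (a message reports how many).
#' @param metric label stored in the output (e.g. `"log2_fc_rna"`).
#' @return data.frame: `cytoband`, `metric`, `median_value`, `n_genes`.
#' @export
band_summary <- function(gene_metric, annotation, metric = "value") {
  band <- annotation$cytoband[match(gene_metric$gene_id,
                                    annotation$gene_id)]
  drop <- is.na(band) | band == "" | is.na(gene_metric$value)
  if (any(drop))
    message(sprintf("band_summary: excluded %d unmapped or missing gene(s)",
                    sum(drop)))
  d <- gene_metric[!drop, , drop = FALSE]
  band <- band[!drop]
  med <- tapply(d$value, band, stats::median)
  n <- tapply(d$value, band, length)
  out <- data.frame(cytoband = names(med), metric = metric,
                    median_value = as.numeric(med),
                    n_genes = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$cytoband), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between RNA and protein abundance across genes
#'
#' Pearson correlation of the per-gene median log2(TPM + pseudocount)
#' against the per-gene median log10 copy number, both medians taken across
#' lines, over genes quantified in both layers.
#'
#' @param rna expression matrix (layer `rna_tpm`).
#' @param copies copy-number matrix (rownames = accessions).
#' @param annotation an `xci_annotation` providing the gene-accession map.
#' @param pseudocount added to TPM before log2 (default 0.01).
#' @return scalar Pearson r (`NA` with a warning if degenerate); attributes
#'   `n_genes`.
#' @export
rna_protein_abundance_correlation <- function(rna, copies, annotation,
                                              pseudocount = 0.01) {
  acc <- annotation$protein_accession[match(rownames(rna),
                                            annotation$gene_id)]
  ok <- !is.na(acc) & acc %in% rownames(copies)
  if (sum(ok) < 3)
    abort("rna_protein_abundance_correlation: fewer than 3 shared genes")
  med_rna <- apply(log2(rna[ok, , drop = FALSE] + pseudocount), 1,
                   stats::median, na.rm = TRUE)
  lc <- copies[acc[ok], , drop = FALSE]
  lc[!is.na(lc) & lc <= 0] <- NA
  med_prot <- apply(log10(lc), 1, stats::median, na.rm = TRUE)
  if (stats::sd(med_rna) == 0 || stats::sd(med_prot, na.rm = TRUE) == 0) {
    warning("rna_protein_abundance_correlation: constant abundance vector",
            call. = FALSE)
    return(NA_real_)
  }
  r <- stats::cor(med_rna, med_prot, use = "complete.obs")
  attr(r, "n_genes") <- sum(ok)
  r
}
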