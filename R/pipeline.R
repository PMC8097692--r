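#' Run the full XCI-erosion analysis pipeline on a cohort bundle
#'
#' Executes, in order: XIST stratification, allele-specific expression,
#' protein-group filtering + proteomic ruler + TMT batch correction,
#' plex capping of the High-XIST set, Low-vs-High differential expression
#' on both layers, chromosome/band aggregation, protein content and
#' ribosome stoichiometry, and subset enrichment with a resampling null.
#' The returned `report` is a pure aggregation: every number in it is
#' recomputable by calling the underlying module function directly.
#'
#' @param bundle an `xci_cohort` (from [generate_cohort()] or assembled
#'   from files read with the `read_*` functions: `sample_sheet`,
#'   `allele_counts`, `rna`, `protein_groups`, `annotation`).
#' @param ase_cfg,strat_cfg,ruler_cfg,de_cfg configuration objects.
#' @param enrich_cfg an [enrichment_config()]; its seed is re-derived from
#'   `seed` so the whole run is reproducible from one root seed.
#' @param seed integer root seed for the stochastic stages.
#' @return list with `report` (JSON-ready summary), `strata`,
#'   `high_retained`, `copies` (batch-corrected), `content`, `de_rna`,
#'   `de_protein`, `chromosome_summary`, `ase_chromosome`,
#'   `subunit_ratio`, `enrichment_copies`, `enrichment_peptides`.
#' @export
run_xci_pipeline <- function(bundle,
                             ase_cfg = ase_config(),
                             strat_cfg = stratify_config(),
                             ruler_cfg = ruler_config(),
                             de_cfg = de_config(),
                             enrich_cfg = enrichment_config(n_iterations = 10000),
                             seed = 1L) {
  sheet <- bundle$sample_sheet
  anno <- bundle$annotation

  ## 1. stratification -----------------------------------------------------
  strata <- stratify_by_xist(bundle$rna, sheet, strat_cfg)
  pct <- stratum_percentages(strata)
  low <- strata$line_id[strata$stratum == "Low"]
  high <- strata$line_id[strata$stratum == "High"]
  males <- sheet$line_id[sheet$donor_sex == "male"]

  ## 2. allele-specific expression -----------------------------------------
  ase_chr <- aggregate_ase(bundle$allele_counts, anno,
                           level = "chromosome", config = ase_cfg)
  ase_x <- ase_chr[ase_chr$key == "X", , drop = FALSE]
  stratum_of <- strata$stratum[match(ase_x$line_id, strata$line_id)]
  median_sec <- vapply(c("Low", "Medium", "High"), function(s) {
    v <- ase_x$secondary_fraction[!is.na(stratum_of) & stratum_of == s]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, 0)

  ## 3. proteomics quantification ------------------------------------------
  pg <- filter_protein_groups(bundle$protein_groups, ruler_cfg)
  copies_raw <- ruler_copy_numbers(pg, anno, ruler_cfg)
  copies <- batch_correct(copies_raw, sheet)
  plex_factors <- attr(copies, "plex_factors")
  high_retained <- cap_plex_replicates(high, copies, sheet, strat_cfg)

  ## 4. protein content and copy sums --------------------------------------
  content <- protein_content_pg(copies)
  groups <- list(low_xist = intersect(low, names(content)),
                 high_xist = intersect(high_retained, names(content)),
                 male = intersect(males, names(content)))
  content_summary <- group_content_summary(content, groups)

  acc_x <- anno$protein_accession[anno$chromosome == "X"]
  acc_auto <- anno$protein_accession[!anno$chromosome %in% c("X", "Y", "MT")]
  sum_over <- function(accs) {
    colSums(copies[intersect(rownames(copies), accs), , drop = FALSE],
            na.rm = TRUE)
  }
  x_sum <- sum_over(acc_x)
  auto_sum <- sum_over(acc_auto)
  med_by_group <- function(v) vapply(groups, function(g) stats::median(v[g]), 0)
  x_med <- med_by_group(x_sum)
  auto_med <- med_by_group(auto_sum)

  ## 5. differential expression --------------------------------------------
  # RNA uses all High lines; the plex cap exists to balance TMT batches and
  # is applied to the protein layer only.
  de_rna <- run_de(bundle$rna, low, high, de_cfg)
  attr(copies, "layer") <- "protein_copies"
  de_protein <- run_de(copies, intersect(low, colnames(copies)),
                       high_retained, de_cfg)

  ## 6. genome-level aggregation -------------------------------------------
  chrom <- summarize_by_chromosome(de_rna, de_protein, anno,
                                   q_threshold = de_cfg$q_threshold)
  auto_rows <- function(layer) {
    chrom[chrom$layer == layer &
            !chrom$chromosome %in% c("X", "Y", "MT"), , drop = FALSE]
  }
  de_counts <- lapply(c(rna = "rna", protein = "protein"), function(l) {
    a <- auto_rows(l)
    x <- chrom[chrom$layer == l & chrom$chromosome == "X", , drop = FALSE]
    list(autosome_n_up = sum(a$n_up), autosome_n_down = sum(a$n_down),
         autosome_n_total = sum(a$n_genes),
         autosome_pct_up = de_percentages(sum(a$n_up), sum(a$n_genes)),
         autosome_pct_down = de_percentages(sum(a$n_down), sum(a$n_genes)),
         x_pct_up = if (nrow(x) > 0)
           de_percentages(sum(x$n_up), sum(x$n_genes)) else NA_real_)
  })
  x_fc_r <- chrom$pearson_r_rna_vs_protein_fc[chrom$chromosome == "X"][1]
  auto_r <- chrom$pearson_r_rna_vs_protein_fc[
    chrom$layer == "rna" & !chrom$chromosome %in% c("X", "Y", "MT")]
  abundance_r <- rna_protein_abundance_correlation(bundle$rna, copies, anno,
                                                   de_cfg$pseudocount)

  ## 7. ribosome stoichiometry ---------------------------------------------
  ratio <- subunit_ratio(copies, anno)
  ratio_med <- med_by_group(ratio)
  ratio_welch <- stats::t.test(ratio[groups$low_xist],
                               ratio[groups$high_xist], var.equal = FALSE)

  ## 8. enrichment ----------------------------------------------------------
  enrich_cfg$seed <- substream_seed(seed, "enrichment")
  gene_of_acc <- anno$gene_id[match(de_protein$gene_id,
                                    anno$protein_accession)]
  rna_dir <- de_rna$direction[match(gene_of_acc, de_rna$gene_id)]
  detected_both <- !is.na(de_protein$log2_fc) & !is.na(rna_dir) &
    !is.na(de_rna$log2_fc[match(gene_of_acc, de_rna$gene_id)])
  universe <- de_protein$gene_id[detected_both]
  subset_acc <- de_protein$gene_id[detected_both &
                                     de_protein$direction == "up" &
                                     rna_dir != "up"]
  med_copies <- apply(copies[universe, , drop = FALSE], 1, stats::median,
                      na.rm = TRUE)
  rup <- stats::setNames(pg$info$razor_unique_peptides,
                         primary_accession(pg))[universe]
  enr_copies <- enrich_subset(med_copies, subset_acc, enrich_cfg)
  enr_rup <- enrich_subset(rup, subset_acc, enrich_cfg)

  ## report ------------------------------------------------------------------
  strip <- function(e) e[c("observed_count", "expected_count", "threshold",
                           "hypergeom_p", "empirical_p", "null_summary",
                           "N", "K", "n")]
  report <- list(
    schema_version = "1.0",
    seed = seed,
    n_lines = nrow(sheet),
    n_female = sum(sheet$donor_sex == "female"),
    strata = list(counts = stats::setNames(as.list(pct$n), pct$stratum),
                  pct = stats::setNames(as.list(pct$pct), pct$stratum),
                  n_high_retained = length(high_retained)),
    median_secondary_fraction = as.list(median_sec),
    plex_factors = as.list(plex_factors),
    protein_content = list(
      median_pg = as.list(med_by_group(content)),
      comparisons = content_summary),
    copy_sums = list(
      x_median = as.list(x_med), autosome_median = as.list(auto_med),
      x_pct_increase_low_vs_high =
        100 * (x_med[["low_xist"]] / x_med[["high_xist"]] - 1),
      autosome_pct_increase_low_vs_high =
        100 * (auto_med[["low_xist"]] / auto_med[["high_xist"]] - 1)),
    de = de_counts,
    correlations = list(
      rna_protein_abundance_r = as.numeric(abundance_r),
      x_fold_change_r = x_fc_r,
      autosome_fold_change_r_median = stats::median(auto_r, na.rm = TRUE)),
    ribosome = list(
      ratio_60S_40S_median = as.list(ratio_med),
      ratio_pct_increase_low_vs_high =
        100 * (ratio_med[["low_xist"]] / ratio_med[["high_xist"]] - 1),
      welch_p = ratio_welch$p.value),
    enrichment = list(copies = strip(enr_copies),
                      peptides = strip(enr_rup)))

  list(report = report, strata = strata, high_retained = high_retained,
       copies = copies, content = content, de_rna = de_rna,
       de_protein = de_protein, chromosome_summary = chrom,
       ase_chromosome = ase_chr, subunit_ratio = ratio,
       enrichment_copies = enr_copies, enrichment_peptides = enr_rup)
}

#' Write a pipeline report as JSON
#'
#' @param report the `report` element of [run_xci_pipeline()]'s result (or
#'   any list of scalars/tables).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
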