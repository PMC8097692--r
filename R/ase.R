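#' ASE configuration
#'
#' @param min_reads_per_snp minimum total read depth for a SNP to enter any
#'   allele-specific expression statistic (default 20, the depth filter used
#'   for heterozygous X-chromosome SNPs).
#' @return an `xci_ase_config` list.
#' @export
ase_config <- function(min_reads_per_snp = 20) {
  if (min_reads_per_snp < 1)
    abort("ase config: min_reads_per_snp must be >= 1")
  structure(list(min_reads_per_snp = min_reads_per_snp),
            class = "xci_ase_config")
}

#' Folded secondary-allele fraction of a single SNP
#'
#' The fraction of reads mapping to the less expressed (secondary) allele:
#' `min(a, b) / (a + b)`, always in [0, 0.5]. Vectorized; no depth filter is
#' applied here (callers exclude SNPs below the threshold rather than
#' erroring).
#'
#' @param allele_a_count,allele_b_count nonnegative read counts.
#' @return numeric vector in [0, 0.5].
#' @export
snp_secondary_fraction <- function(allele_a_count, allele_b_count) {
  if (any(allele_a_count < 0, na.rm = TRUE) ||
      any(allele_b_count < 0, na.rm = TRUE))
    abort("allele counts must be nonnegative")
  pmin(allele_a_count, allele_b_count) /
    (allele_a_count + allele_b_count)
}

passing_snps <- function(counts, config) {
  counts$allele_a_count + counts$allele_b_count >= config$min_reads_per_snp
}

#' Per-gene, per-line secondary-allele fraction
#'
#' For each (line, gene), SNPs with total depth below the threshold are
#' excluded; the gene value is the unweighted arithmetic mean of the folded
#' per-SNP fractions. Genes/lines with no passing SNP are absent from the
#' result (not measurable in that line), never an error.
#'
#' @param counts an `xci_allele_counts` table.
#' @param config an [ase_config()].
#' @return data.frame: `line_id`, `gene_id`, `secondary_fraction`,
#'   `n_snps_used`.
#' @export
gene_ase_fraction <- function(counts, config = ase_config()) {
  keep <- passing_snps(counts, config)
  d <- counts[keep, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(line_id = character(0), gene_id = character(0),
                      secondary_fraction = numeric(0),
                      n_snps_used = integer(0), stringsAsFactors = FALSE))
  frac <- snp_secondary_fraction(d$allele_a_count, d$allele_b_count)
  key <- interaction(d$line_id, d$gene_id, drop = TRUE, sep = "\r")
  mean_f <- tapply(frac, key, mean)
  n <- tapply(frac, key, length)
  parts <- strsplit(names(mean_f), "\r", fixed = TRUE)
  out <- data.frame(line_id = vapply(parts, `[`, "", 1),
                    gene_id = vapply(parts, `[`, "", 2),
                    secondary_fraction = as.numeric(mean_f),
                    n_snps_used = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$line_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate secondary-allele fractions over cytobands or chromosomes
#'
#' Default pooling averages the folded fractions of all passing SNPs in the
#' region directly (not a mean of gene means), per line; `"gene_mean"`
#' averages per-gene values instead. Regions with zero passing SNPs are
#' omitted.
#'
#' @param counts an `xci_allele_counts` table.
#' @param annotation an `xci_annotation` table mapping genes to bands and
#'   chromosomes.
#' @param level `"chromosome"` or `"band"`.
#' @param config an [ase_config()].
#' @param snp_pooling `"pooled"` (default) or `"gene_mean"`.
#' @return data.frame: `level`, `line_id`, `key`, `secondary_fraction`,
#'   `n_snps_used`.
#' @export
aggregate_ase <- function(counts, annotation,
                          level = c("chromosome", "band"),
                          config = ase_config(),
                          snp_pooling = c("pooled", "gene_mean")) {
  level <- match.arg(level)
  snp_pooling <- match.arg(snp_pooling)
  region_of <- function(gene_id) {
    i <- match(gene_id, annotation$gene_id)
    if (anyNA(i))
      abort("aggregate_ase: gene '%s' missing from annotation",
            gene_id[is.na(i)][1])
    if (level == "chromosome") annotation$chromosome[i]
    else annotation$cytoband[i]
  }
  if (snp_pooling == "pooled") {
    keep <- passing_snps(counts, config)
    d <- counts[keep, , drop = FALSE]
    if (nrow(d) == 0) value <- n <- numeric(0)
    frac <- snp_secondary_fraction(d$allele_a_count, d$allele_b_count)
    reg <- region_of(d$gene_id)
    key <- interaction(d$line_id, reg, drop = TRUE, sep = "\r")
    value <- tapply(frac, key, mean)
    n <- tapply(frac, key, length)
  } else {
    g <- gene_ase_fraction(counts, config)
    reg <- region_of(g$gene_id)
    key <- interaction(g$line_id, reg, drop = TRUE, sep = "\r")
    value <- tapply(g$secondary_fraction, key, mean)
    n <- tapply(g$n_snps_used, key, sum)
  }
  parts <- strsplit(names(value), "\r", fixed = TRUE)
  out <- data.frame(level = level,
                    line_id = vapply(parts, `[`, "", 1),
                    key = vapply(parts, `[`, "", 2),
                    secondary_fraction = as.numeric(value),
                    n_snps_used = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$line_id, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the primary (more expressed) allele per gene and line
#'
#' The primary allele is the one with the larger read count summed over the
#' gene's passing SNPs; ties go to `allele_a` (deterministic tie-break; the
#' folded fraction statistic is unaffected).
#'
#' @param counts an `xci_allele_counts` table.
#' @param config an [ase_config()].
#' @return data.frame: `line_id`, `gene_id`, `primary_allele`
#'   (`"allele_a"`/`"allele_b"`), `sum_a`, `sum_b`.
#' @export
assign_primary_allele <- function(counts, config = ase_config()) {
  keep <- passing_snps(counts, config)
  d <- counts[keep, , drop = FALSE]
  key <- interaction(d$line_id, d$gene_id, drop = TRUE, sep = "\r")
  sum_a <- tapply(d$allele_a_count, key, sum)
  sum_b <- tapply(d$allele_b_count, key, sum)
  parts <- strsplit(names(sum_a), "\r", fixed = TRUE)
  out <- data.frame(line_id = vapply(parts, `[`, "", 1),
                    gene_id = vapply(parts, `[`, "", 2),
                    primary_allele = ifelse(sum_a >= sum_b,
                                            "allele_a", "allele_b"),
                    sum_a = as.numeric(sum_a), sum_b = as.numeric(sum_b),
                    stringsAsFactors = FALSE)
  out <- out[order(out$line_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
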