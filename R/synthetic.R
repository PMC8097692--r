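#' Configuration for the synthetic iPSC cohort generator
#'
#' Defaults reproduce the study conditions of the cohort the pipeline is
#' designed for: 74 female lines split 30 Low / 35 High / 9 Medium XIST plus
#' 46 male lines, 10-plex TMT batches, median secondary-allele fractions of
#' 0.5% in high-XIST and 22.6% in low-XIST lines, a 1.27-fold X-linked
#' RNA-and-protein amplification and a 1.13-fold autosomal protein-only
#' (global translation) amplification in eroded (low-XIST) lines.
#'
#' @param n_female_low,n_female_high,n_female_medium,n_male line counts per
#'   XIST stratum and for males.
#' @param n_genes_autosome,n_genes_x gene counts (histone anchor genes are
#'   added on top of `n_genes_autosome`).
#' @param n_snps_per_gene heterozygous SNPs simulated per X-linked gene.
#' @param mean_depth mean read depth per SNP (Poisson).
#' @param secondary_fraction_high,secondary_fraction_low folded
#'   secondary-allele fractions in [0, 0.5] injected per stratum. Medium
#'   lines use the high-XIST value (XCI still intact while XIST detectable).
#' @param x_rna_amplification fold applied to X-linked genes of low-XIST
#'   lines, on both RNA and protein layers.
#' @param autosome_protein_amplification fold applied to autosomal,
#'   non-histone proteins of low-XIST lines (protein layer only).
#' @param plex_size lines per TMT plex (10-plex chemistry).
#' @param plex_effect_sd log-scale SD of the multiplicative plex factors.
#' @param n_histones number of histone anchor proteins.
#' @param noise_sd_rna,noise_sd_protein log-scale (natural log) SDs of the
#'   multiplicative measurement noise on TPM and reporter intensities.
#' @param rna_protein_link_sd log10-scale SD of the gene-level scatter
#'   between RNA and protein baseline abundance; controls the RNA-protein
#'   abundance correlation of the cohort.
#' @param x_fold_gene_sd log-scale SD of the mean-one lognormal per-gene
#'   multiplier on `x_rna_amplification`: XCI erosion affects X-linked genes
#'   heterogeneously, and the per-gene fold is shared between the RNA and
#'   protein layers (this drives the X fold-change concordance).
#' @param seed integer root seed; all tables draw from named substreams of it.
#' @return an `xci_cohort_config` list.
#' @export
cohort_config <- function(n_female_low = 30, n_female_high = 35,
                          n_female_medium = 9, n_male = 46,
                          n_genes_autosome = 3000, n_genes_x = 150,
                          n_snps_per_gene = 3, mean_depth = 60,
                          secondary_fraction_high = 0.005,
                          secondary_fraction_low = 0.226,
                          x_rna_amplification = 1.27,
                          autosome_protein_amplification = 1.13,
                          plex_size = 10, plex_effect_sd = 0.1,
                          n_histones = 20,
                          noise_sd_rna = 0.25, noise_sd_protein = 0.15,
                          rna_protein_link_sd = 0.5,
                          x_fold_gene_sd = 0.2,
                          seed = 1L) {
  cfg <- list(n_female_low = n_female_low, n_female_high = n_female_high,
              n_female_medium = n_female_medium, n_male = n_male,
              n_genes_autosome = n_genes_autosome, n_genes_x = n_genes_x,
              n_snps_per_gene = n_snps_per_gene, mean_depth = mean_depth,
              secondary_fraction_high = secondary_fraction_high,
              secondary_fraction_low = secondary_fraction_low,
              x_rna_amplification = x_rna_amplification,
              autosome_protein_amplification = autosome_protein_amplification,
              plex_size = plex_size, plex_effect_sd = plex_effect_sd,
              n_histones = n_histones, noise_sd_rna = noise_sd_rna,
              noise_sd_protein = noise_sd_protein,
              rna_protein_link_sd = rna_protein_link_sd,
              x_fold_gene_sd = x_fold_gene_sd,
              seed = as.integer(seed))
  counts <- c("n_female_low", "n_female_high", "n_female_medium", "n_male",
              "n_genes_autosome", "n_genes_x", "n_snps_per_gene",
              "plex_size", "n_histones")
  for (f in counts) if (cfg[[f]] < 1 || cfg[[f]] != floor(cfg[[f]]))
    abort("cohort config: %s must be a positive integer", f)
  for (f in c("secondary_fraction_high", "secondary_fraction_low"))
    if (cfg[[f]] < 0 || cfg[[f]] > 0.5)
      abort("cohort config: %s must lie in [0, 0.5]", f)
  for (f in c("x_rna_amplification", "autosome_protein_amplification"))
    if (cfg[[f]] <= 0) abort("cohort config: %s must be > 0", f)
  if (cfg$mean_depth <= 0) abort("cohort config: mean_depth must be > 0")
  if (cfg$n_genes_x * cfg$n_snps_per_gene < 1)
    abort("cohort config: configuration implies 0 heterozygous SNPs for female lines")
  class(cfg) <- "xci_cohort_config"
  cfg
}

# Canonical molecular weights (Da) of the five histone families, cycled over
# the anchor proteins. Values: H1.0, H2A type 1, H2B type 1, H3.1, H4.
HISTONE_MW <- c(20863, 14091, 13906, 15404, 11367)

#' Generate a complete synthetic iPSC cohort
#'
#' Produces every table the pipeline consumes (sample sheet, allele counts,
#' TPM matrix, MaxQuant-style protein groups, annotation) plus a `truth`
#' record of all injected parameters, so downstream stages can be tested for
#' parameter recovery without any external download.
#'
#' The generative model, per line and gene:
#' * XIST log2 TPM is drawn inside the Low (< 1), Medium (1-2.75) and
#'   High (> 2.75) stratification windows, and near zero for males.
#' * Gene baseline RNA log2 TPM ~ Normal(5, 1.8); protein baseline
#'   log10 copies = 5.05 + 0.35 x (log2 TPM - 5) +
#'   Normal(0, rna_protein_link_sd), the abundance deviation clamped at
#'   +-3 SD (proteome dynamic range spans roughly five orders of
#'   magnitude). This couples protein to RNA abundance at a realistic
#'   correlation and gives per-cell contents near 180 pg.
#' * Low-XIST lines amplify X-linked genes on both layers (the per-gene
#'   fold, mean `x_rna_amplification`, is shared between layers) and
#'   autosomal non-histone proteins only
#'   (`autosome_protein_amplification`).
#' * Histone anchors carry exactly 6.5 pg of protein mass per cell (the
#'   diploid DNA mass the proteomic ruler assumes), split equally by mass.
#' * Reporter intensity = copies x MW x plex factor x lognormal noise,
#'   where the noise SD shrinks with peptide support (precision improves
#'   with the number of quantified peptides, which is what links
#'   significance to abundance downstream); the plex factor applies to
#'   non-histone rows (batch effects shift the sampled proteome relative
#'   to the histone anchor, which is what the downstream batch correction
#'   estimates and removes).
#' * Allele counts: per SNP, depth ~ Poisson(mean_depth) and minor reads ~
#'   Binomial(depth, stratum secondary fraction); male lines are
#'   hemizygous (all reads on one allele).
#'
#' @param config an [cohort_config()] object.
#' @return an `xci_cohort` list: `sample_sheet`, `allele_counts`, `rna`,
#'   `protein_groups`, `annotation`, `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "xci_cohort_config"))
  seed <- config$seed

  ## ---- lines ----------------------------------------------------------
  n_f <- config$n_female_low + config$n_female_high + config$n_female_medium
  n_lines <- n_f + config$n_male
  line_id <- sprintf("L%03d", seq_len(n_lines))
  stratum <- c(rep("Low", config$n_female_low),
               rep("High", config$n_female_high),
               rep("Medium", config$n_female_medium),
               rep(NA_character_, config$n_male))
  sex <- c(rep("female", n_f), rep("male", config$n_male))
  n_plex <- ceiling(n_lines / config$plex_size)
  # round-robin plexing: deterministic, even stratum mix per plex
  plex <- sprintf("PT%02d", ((seq_len(n_lines) - 1) %% n_plex) + 1)
  sheet <- new_sample_sheet(line_id, sex, plex,
                            donor_id = sprintf("D%03d", seq_len(n_lines)))

  ## ---- genes and annotation ------------------------------------------
  n_auto <- config$n_genes_autosome
  n_x <- config$n_genes_x
  n_hist <- config$n_histones
  n_rib60 <- min(47, max(1, floor(n_auto * 0.02)))
  n_rib40 <- min(33, max(1, floor(n_auto * 0.015)))
  n_ribbio <- min(20, max(1, floor(n_auto * 0.01)))
  auto_gene <- sprintf("GA%04d", seq_len(n_auto))
  auto_gene[seq_len(n_rib60)] <- sprintf("RPL%02d", seq_len(n_rib60))
  auto_gene[n_rib60 + seq_len(n_rib40)] <- sprintf("RPS%02d", seq_len(n_rib40))
  auto_gene[n_rib60 + n_rib40 + seq_len(n_ribbio)] <-
    sprintf("RBG%02d", seq_len(n_ribbio))
  hist_gene <- sprintf("HIST%02d", seq_len(n_hist))
  x_gene <- sprintf("GX%04d", seq_len(n_x))
  gene_id <- c(auto_gene, hist_gene, x_gene, "XIST")
  n_genes <- length(gene_id)

  anno <- with_substream(seed, "annotation", {
    auto_chr <- as.character(sample(1:22, n_auto, replace = TRUE))
    band_arm <- sample(c("p11", "p12", "q11", "q12", "q21", "q22"),
                       n_auto, replace = TRUE)
    x_band <- sample(c("Xp11", "Xp22", "Xq13", "Xq23", "Xq26"),
                     n_x, replace = TRUE)
    data.frame(
      gene_id = gene_id,
      protein_accession = c(sprintf("P%05d", seq_len(n_genes - 1)), NA),
      chromosome = c(auto_chr, rep("6", n_hist), rep("X", n_x), "X"),
      cytoband = c(paste0(auto_chr, band_arm), rep("6p22", n_hist),
                   x_band, "Xq13"),
      ribosome_60S = gene_id %in% auto_gene[seq_len(n_rib60)],
      ribosome_40S = gene_id %in% auto_gene[n_rib60 + seq_len(n_rib40)],
      ribosome_biogenesis =
        gene_id %in% auto_gene[n_rib60 + n_rib40 + seq_len(n_ribbio)],
      histone = gene_id %in% hist_gene,
      stringsAsFactors = FALSE)
  })
  annotation <- new_annotation(anno)

  ## ---- per-line injected effects -------------------------------------
  is_low <- !is.na(stratum) & stratum == "Low"
  sec_frac <- ifelse(sex == "male", 0,
                     ifelse(is_low, config$secondary_fraction_low,
                            config$secondary_fraction_high))
  auto_fold_line <- ifelse(is_low, config$autosome_protein_amplification, 1)
  # erosion hits X-linked genes heterogeneously; the per-gene fold (mean-one
  # lognormal multiplier on the configured amplification) is shared between
  # the RNA and protein layers
  x_gene_fold <- with_substream(seed, "x_gene_folds", {
    s <- config$x_fold_gene_sd
    config$x_rna_amplification * exp(stats::rnorm(n_x, -s^2 / 2, s))
  })
  names(x_gene_fold) <- x_gene

  ## ---- gene baselines -------------------------------------------------
  coding <- gene_id[gene_id != "XIST"]
  is_hist <- coding %in% hist_gene
  mw_da <- with_substream(seed, "mw", {
    mw <- exp(stats::rnorm(length(coding), log(50000), 0.45))
    mw[is_hist] <- HISTONE_MW[((seq_len(n_hist) - 1) %% length(HISTONE_MW)) + 1]
    mw
  })
  names(mw_da) <- coding
  # histone anchors carry exactly the diploid DNA mass (6.5 pg), split
  # equally by mass, so ruler estimates recover the truth up to noise
  hist_copies <- (6.5e-12 * AVOGADRO) / (n_hist * mw_da[is_hist])

  base_log2tpm <- with_substream(seed, "rna_baseline",
                                 stats::rnorm(n_genes - 1, mean = 5, sd = 1.8))
  names(base_log2tpm) <- gene_id[-n_genes]
  # histone transcripts are among the most abundant mRNAs; anchor their RNA
  # baseline on the same abundance relation the rest of the genes follow
  base_log2tpm[hist_gene] <- 5 + (log10(hist_copies) - 5.05) / 0.35
  xist_log2 <- with_substream(seed, "xist", {
    v <- numeric(n_lines)
    v[is_low] <- stats::runif(sum(is_low), -5, 0.9)
    hi <- !is.na(stratum) & stratum == "High"
    v[hi] <- stats::runif(sum(hi), 2.8, 6)
    md <- !is.na(stratum) & stratum == "Medium"
    v[md] <- stats::runif(sum(md), 1.05, 2.70)
    v[sex == "male"] <- stats::runif(sum(sex == "male"), -7, -5)
    v
  })
  is_x_gene <- gene_id %in% x_gene
  rna <- with_substream(seed, "rna_noise", {
    m <- matrix(0, nrow = n_genes, ncol = n_lines,
                dimnames = list(gene_id, line_id))
    for (j in seq_len(n_lines)) {
      mu <- 2^base_log2tpm
      if (is_low[j])
        mu[is_x_gene[-n_genes]] <- mu[is_x_gene[-n_genes]] * x_gene_fold
      m[-n_genes, j] <- mu * exp(stats::rnorm(n_genes - 1, 0,
                                              config$noise_sd_rna))
    }
    m["XIST", ] <- pmax(2^xist_log2 - 0.01, 0)
    m
  })
  rna <- new_expression_matrix(rna, "rna_tpm")

  ## ---- protein layer --------------------------------------------------
  base_copies <- with_substream(seed, "protein_baseline", {
    # abundance deviation from the grand median, clamped at +-3 SD: proteome
    # copy numbers span ~5 orders of magnitude, not unboundedly more
    dev <- 0.35 * (base_log2tpm[coding] - 5) +
      stats::rnorm(length(coding), 0, config$rna_protein_link_sd)
    sd_tot <- sqrt((0.35 * 1.8)^2 + config$rna_protein_link_sd^2)
    dev <- pmax(pmin(dev, 3 * sd_tot), -3 * sd_tot)
    c0 <- 10^(5.05 + dev)
    c0[is_hist] <- hist_copies
    c0
  })
  is_x_coding <- coding %in% x_gene
  is_auto_coding <- !is_x_coding & !is_hist
  copies_truth <- matrix(0, nrow = length(coding), ncol = n_lines,
                         dimnames = list(coding, line_id))
  for (j in seq_len(n_lines)) {
    cj <- base_copies
    if (is_low[j]) cj[is_x_coding] <- cj[is_x_coding] * x_gene_fold
    cj[is_auto_coding] <- cj[is_auto_coding] * auto_fold_line[j]
    copies_truth[, j] <- cj
  }

  rup <- with_substream(seed, "rup", {
    1 + stats::rpois(length(coding),
                     pmax(0.5, 6 * (log10(base_copies) - 2.9)))
  })
  plex_factors <- with_substream(seed, "plex", {
    f <- exp(stats::rnorm(n_plex, 0, config$plex_effect_sd))
    names(f) <- sprintf("PT%02d", seq_len(n_plex))
    f
  })
  intensity <- with_substream(seed, "intensity_noise", {
    # measurement precision improves with peptide support, the usual TMT
    # behaviour; this is what links significance to abundance downstream
    sd_i <- config$noise_sd_protein * sqrt(10 / (4 + rup))
    noise <- matrix(exp(stats::rnorm(length(coding) * n_lines, 0, sd_i)),
                    nrow = length(coding))
    line_scale <- exp(stats::rnorm(n_lines, 0, 0.2))  # arbitrary per-line
    fac <- plex_factors[plex]
    I <- copies_truth * mw_da * noise
    I[!is_hist, ] <- sweep(I[!is_hist, , drop = FALSE], 2, fac, `*`)
    sweep(I, 2, line_scale, `*`)
  })

  # a few QC-flagged decoy rows exercise the filtering stage
  n_decoy <- 6
  decoy_info <- data.frame(
    accessions = sprintf("DEC%02d", seq_len(n_decoy)),
    gene_name = sprintf("DEC%02d", seq_len(n_decoy)),
    mw_da = rep(30000, n_decoy),
    razor_unique_peptides = rep(5, n_decoy),
    is_contaminant = rep(c(TRUE, FALSE, FALSE), 2),
    is_reverse = rep(c(FALSE, TRUE, FALSE), 2),
    is_only_site = rep(c(FALSE, FALSE, TRUE), 2),
    stringsAsFactors = FALSE)
  acc <- annotation$protein_accession[match(coding, annotation$gene_id)]
  info <- rbind(
    data.frame(accessions = acc, gene_name = coding, mw_da = unname(mw_da),
               razor_unique_peptides = rup,
               is_contaminant = FALSE, is_reverse = FALSE,
               is_only_site = FALSE, stringsAsFactors = FALSE),
    decoy_info)
  decoy_I <- matrix(1e5, nrow = n_decoy, ncol = n_lines)
  intensity_all <- rbind(intensity, decoy_I)
  rownames(intensity_all) <- info$accessions
  colnames(intensity_all) <- line_id
  protein_groups <- new_protein_groups(info, intensity_all)

  ## ---- allele counts --------------------------------------------------
  allele <- with_substream(seed, "allele", {
    n_snp <- config$n_snps_per_gene
    # one row per (gene, line, snp); gene varies slowest, snp fastest
    g_idx <- rep(seq_len(n_x), each = n_lines * n_snp)
    j_idx <- rep(rep(seq_len(n_lines), each = n_snp), times = n_x)
    s_idx <- rep(seq_len(n_snp), times = n_x * n_lines)
    n_rows <- length(g_idx)
    depth <- pmax(stats::rpois(n_rows, config$mean_depth), 1)
    b <- stats::rbinom(n_rows, depth, sec_frac[j_idx])
    a <- depth - b
    male <- sex[j_idx] == "male"
    a[male] <- depth[male]; b[male] <- 0
    # which physical allele is the eroded one is arbitrary per (gene, line)
    swap <- rep(stats::runif(n_x * n_lines) < 0.5, each = n_snp) & !male
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(line_id = line_id[j_idx], gene_id = x_gene[g_idx],
               contig = "X", position = g_idx * 10000 + s_idx * 100,
               allele_a_count = a, allele_b_count = b,
               stringsAsFactors = FALSE)
  })
  allele_counts <- new_allele_counts(allele)

  truth <- list(
    config = config,
    lines = data.frame(line_id = line_id, donor_sex = sex,
                       stratum = stratum, tmt_plex = plex,
                       secondary_fraction = sec_frac,
                       x_amplified = is_low,
                       autosome_protein_fold = auto_fold_line,
                       xist_log2tpm = xist_log2, stringsAsFactors = FALSE),
    plex_factors = plex_factors,
    genes = data.frame(gene_id = coding, mw_da = unname(mw_da),
                       base_copies = unname(base_copies),
                       base_log2tpm = unname(base_log2tpm[coding]),
                       razor_unique_peptides = rup,
                       x_fold = ifelse(is_x_coding,
                                       x_gene_fold[coding], 1),
                       stringsAsFactors = FALSE),
    copies = copies_truth)

  structure(list(sample_sheet = sheet, allele_counts = allele_counts,
                 rna = rna, protein_groups = protein_groups,
                 annotation = annotation, truth = truth),
            class = "xci_cohort")
}

#' Generate a null cohort for type-I-error calibration
#'
#' Identical to [generate_cohort()] but all amplification folds are forced
#' to 1 and the secondary-allele fraction is equal across strata, so any
#' Low-vs-High difference found downstream is a false positive.
#'
#' @param config an [cohort_config()] object.
#' @return an `xci_cohort` whose `truth$null` is `TRUE`.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "xci_cohort_config"))
  config$x_rna_amplification <- 1
  config$x_fold_gene_sd <- 0
  config$autosome_protein_amplification <- 1
  config$secondary_fraction_low <- config$secondary_fraction_high
  out <- generate_cohort(config)
  out$truth$null <- TRUE
  out
}

#' Write all tables of a cohort bundle to a directory
#'
#' @param bundle an `xci_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "xci_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(bundle$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_table(bundle$allele_counts, file.path(dir, "allele_counts.tsv"))
  write_table(bundle$rna, file.path(dir, "rna_tpm.tsv"))
  write_table(bundle$annotation, file.path(dir, "annotation.tsv"))
  write_table(bundle$protein_groups, file.path(dir, "protein_groups.tsv"))
  invisible(dir)
}
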