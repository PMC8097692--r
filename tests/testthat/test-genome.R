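fake_de <- function(gene_id, fc, q = rep(1, length(gene_id))) {
  out <- data.frame(gene_id = gene_id, log2_fc = fc, t_stat = NA_real_,
                    df = NA_real_, p_value = q, q_value = q,
                    direction = ifelse(q <= 0.05 & fc > 0, "up",
                                       ifelse(q <= 0.05 & fc < 0, "down",
                                              "ns")),
                    n_low = 3L, n_high = 3L, stringsAsFactors = FALSE)
  class(out) <- c("xci_de", "data.frame")
  out
}

test_that("percentages reproduce the printed counts with half-up rounding", {
  expect_equal(de_percentages(1087, 12042), 9.0)
  expect_equal(de_percentages(1344, 12042), 11.2)
  expect_equal(de_percentages(107, 8593), 1.2)
  expect_equal(de_percentages(0, 100), 0)
  expect_error(de_percentages(1, 0), "> 0")
  expect_error(de_percentages(5, 4), "exceeds")
})

test_that("chromosome summaries aggregate medians, SEM, counts and r", {
  genes <- paste0("G", 1:10)
  anno <- make_anno(genes, rep(c("1", "X"), each = 5),
                    cytoband = rep(c("1q11", "Xq23"), each = 5),
                    protein_accession = paste0("P", 1:10))
  fc_rna <- c(1, 2, 3, 4, 5, 0.1, 0.2, 0.3, 0.4, 0.5)
  fc_prot <- c(5, 4, 3, 2, 1, 0.1, 0.2, 0.3, 0.4, 0.5)
  de_rna <- fake_de(genes, fc_rna, q = rep(0.01, 10))
  de_prot <- fake_de(paste0("P", 1:10), fc_prot, q = rep(0.5, 10))
  out <- summarize_by_chromosome(de_rna, de_prot, anno)

  chr1_rna <- out[out$chromosome == "1" & out$layer == "rna", ]
  expect_equal(chr1_rna$median_log2_fc, median(fc_rna[1:5]))
  expect_equal(chr1_rna$sem, sd(fc_rna[1:5]) / sqrt(5))
  expect_equal(chr1_rna$n_up, 5L)
  expect_equal(chr1_rna$pct_up, 100)
  # anti-correlated on chr1, perfectly correlated on X
  expect_equal(chr1_rna$pearson_r_rna_vs_protein_fc, -1)
  chrx <- out[out$chromosome == "X" & out$layer == "protein", ]
  expect_equal(chrx$pearson_r_rna_vs_protein_fc, 1)
  expect_equal(chrx$n_up, 0L)

  # fewer than 3 shared genes: r undefined, medians still present
  small <- summarize_by_chromosome(fake_de(genes[1:2], c(1, 2)),
                                   fake_de(paste0("P", 1:2), c(1, 2)),
                                   anno)
  expect_true(all(is.na(small$pearson_r_rna_vs_protein_fc)))
  expect_equal(nrow(small), 2)
})

test_that("chromosome medians ignore genes with missing fold changes", {
  genes <- paste0("G", 1:4)
  anno <- make_anno(genes, rep("2", 4), cytoband = rep("2q11", 4),
                    protein_accession = paste0("P", 1:4))
  a <- summarize_by_chromosome(fake_de(genes, c(1, 2, 3, NA)),
                               fake_de(paste0("P", 1:4), c(1, 2, 3, NA)),
                               anno)
  b <- summarize_by_chromosome(fake_de(genes[1:3], c(1, 2, 3)),
                               fake_de(paste0("P", 1:3), c(1, 2, 3)),
                               anno)
  expect_equal(a$median_log2_fc, b$median_log2_fc)
  expect_equal(a$n_genes, b$n_genes)
})

test_that("band summaries take per-band medians over mapped genes", {
  anno <- make_anno(paste0("G", 1:4), c("5", "5", "5", "7"),
                    cytoband = c("5q31", "5q31", "5q31", "7p11"))
  gm <- data.frame(gene_id = paste0("G", 1:4), value = c(0.1, 0.3, 0.5, 2))
  out <- band_summary(gm, anno, metric = "log2_fc_rna")
  expect_equal(out$median_value[out$cytoband == "5q31"], 0.3)
  expect_equal(out$median_value[out$cytoband == "7p11"], 2)
  expect_equal(out$n_genes, c(3L, 1L))

  # unmapped genes are excluded with a message
  gm2 <- rbind(gm, data.frame(gene_id = "G99", value = 9))
  expect_message(out2 <- band_summary(gm2, anno), "excluded 1")
  expect_equal(out2$median_value, out$median_value)

  # random fixture against a sort-based median oracle
  set.seed(21)
  vals <- rnorm(30)
  band_of <- stats::setNames(rep(c("9p11", "9q22", "9q34"), 10),
                             paste0("R", 1:30))
  annor <- make_anno(names(band_of), rep("9", 30), cytoband = band_of)
  gmr <- data.frame(gene_id = names(band_of), value = vals)
  outr <- band_summary(gmr, annor)
  for (bnd in unique(band_of)) {
    v <- sort(vals[band_of == bnd])
    oracle <- (v[5] + v[6]) / 2
    expect_equal(outr$median_value[outr$cytoband == bnd], oracle)
  }
})

test_that("abundance correlation is 1 for copies proportional to TPM", {
  genes <- paste0("G", 1:6)
  anno <- make_anno(genes, rep("3", 6), cytoband = rep("3q11", 6))
  tpm <- matrix(2^seq(2, 12, 2), 6, 2, dimnames = list(genes, c("L1", "L2")))
  rna <- make_expr(tpm)
  copies <- tpm * 1000
  rownames(copies) <- paste0("P", 1:6)
  expect_equal(as.numeric(rna_protein_abundance_correlation(rna, copies, anno)),
               1, tolerance = 1e-6)
  anti <- copies[6:1, ]
  rownames(anti) <- paste0("P", 1:6)
  expect_lt(rna_protein_abundance_correlation(rna, anti, anno), 0)
})

test_that("abundance correlation rises as the RNA-protein link tightens", {
  r_at <- function(link_sd) {
    b <- generate_cohort(small_config(rna_protein_link_sd = link_sd,
                                      seed = 33))
    cp <- ruler_copy_numbers(filter_protein_groups(b$protein_groups),
                             b$annotation)
    rna_protein_abundance_correlation(b$rna, cp, b$annotation)
  }
  rs <- vapply(c(1.2, 0.5, 0.05), r_at, 0)
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.95)
})
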