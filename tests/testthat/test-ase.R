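test_that("per-SNP secondary fractions fold to [0, 0.5]", {
  expect_equal(snp_secondary_fraction(40, 0), 0)
  expect_equal(snp_secondary_fraction(20, 20), 0.5)
  expect_equal(snp_secondary_fraction(30, 10), 0.25)
  expect_equal(snp_secondary_fraction(25, 15), 0.375)
  expect_error(snp_secondary_fraction(-1, 5), "nonnegative")
})

test_that("gene fractions average passing SNPs and drop shallow ones", {
  # two passing SNPs with fractions 0.25 and 0.375 -> mean 0.3125
  ac <- make_counts(rep("L1", 2), rep("G1", 2), a = c(30, 25), b = c(10, 15))
  g <- gene_ase_fraction(ac)
  expect_equal(g$secondary_fraction, 0.3125)
  expect_equal(g$n_snps_used, 2L)

  # a single monoallelic SNP
  g0 <- gene_ase_fraction(make_counts("L1", "G1", a = 40, b = 0))
  expect_equal(g0$secondary_fraction, 0)

  # 19 total reads: below the 20-read depth filter, gene not measurable
  g19 <- gene_ase_fraction(make_counts("L1", "G1", a = 14, b = 5))
  expect_equal(nrow(g19), 0)
})

test_that("folding is symmetric under allele swaps", {
  set.seed(42)
  n <- 60
  ac <- make_counts(sample(c("L1", "L2"), n, TRUE),
                    sample(c("G1", "G2", "G3"), n, TRUE),
                    a = rpois(n, 30), b = rpois(n, 10),
                    position = seq_len(n) * 10)
  swapped <- ac
  swapped$allele_a_count <- ac$allele_b_count
  swapped$allele_b_count <- ac$allele_a_count
  expect_equal(gene_ase_fraction(ac), gene_ase_fraction(swapped))
})

test_that("raising a minority count never lowers the gene fraction", {
  a <- c(35, 28); b <- c(5, 12)
  base <- gene_ase_fraction(make_counts(rep("L1", 2), rep("G1", 2), a, b))
  for (delta in 1:5) {
    g <- gene_ase_fraction(make_counts(rep("L1", 2), rep("G1", 2),
                                       a - c(delta, 0), b + c(delta, 0)))
    expect_gte(g$secondary_fraction, base$secondary_fraction)
    base <- g
  }
})

test_that("gene fractions match a brute-force oracle on random tables", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40
    ac <- make_counts(sample(paste0("L", 1:3), n, TRUE),
                      sample(paste0("G", 1:4), n, TRUE),
                      a = rpois(n, 25), b = rpois(n, 8),
                      position = seq_len(n) * 10)
    got <- gene_ase_fraction(ac)
    # oracle: plain loop over every (line, gene) pair
    for (i in seq_len(nrow(got))) {
      rows <- ac[ac$line_id == got$line_id[i] & ac$gene_id == got$gene_id[i], ]
      tot <- rows$allele_a_count + rows$allele_b_count
      keep <- tot >= 20
      frs <- pmin(rows$allele_a_count, rows$allele_b_count)[keep] / tot[keep]
      expect_equal(got$secondary_fraction[i], mean(frs))
      expect_equal(got$n_snps_used[i], sum(keep))
    }
  }
})

test_that("regional aggregation pools SNPs, not gene means", {
  anno <- make_anno(c("G1", "G2"), c("X", "X"), cytoband = c("Xq23", "Xq23"))
  # G1 has one SNP at 0.1, G2 one at 0.3 -> band mean 0.2
  ac <- make_counts(rep("L1", 2), c("G1", "G2"), a = c(90, 70), b = c(10, 30))
  band <- aggregate_ase(ac, anno, level = "band")
  expect_equal(band$key, "Xq23")
  expect_equal(band$secondary_fraction, 0.2)
  expect_equal(band$n_snps_used, 2L)

  # pooled vs gene-mean differ when SNP counts are unbalanced
  ac2 <- make_counts(rep("L1", 3), c("G1", "G1", "G2"),
                     a = c(90, 90, 70), b = c(10, 10, 30))
  pooled <- aggregate_ase(ac2, anno, level = "chromosome")
  bygene <- aggregate_ase(ac2, anno, level = "chromosome",
                          snp_pooling = "gene_mean")
  expect_equal(pooled$secondary_fraction, (0.1 + 0.1 + 0.3) / 3)
  expect_equal(bygene$secondary_fraction, (0.1 + 0.3) / 2)

  # all-monoallelic chromosome is exactly 0
  mono <- aggregate_ase(make_counts("L1", "G1", a = 50, b = 0), anno)
  expect_equal(mono$secondary_fraction, 0)

  # permutation invariance
  perm <- ac2[c(3, 1, 2), ]
  expect_equal(aggregate_ase(xcierosion:::new_allele_counts(perm), anno),
               pooled)
})

test_that("primary-allele assignment sums passing SNPs with a tie to allele_a", {
  ac <- make_counts(rep("L1", 2), rep("G1", 2), a = c(60, 40), b = c(20, 10))
  expect_equal(assign_primary_allele(ac)$primary_allele, "allele_a")
  acb <- make_counts(rep("L1", 2), rep("G1", 2), a = c(20, 10), b = c(60, 40))
  expect_equal(assign_primary_allele(acb)$primary_allele, "allele_b")
  tie <- make_counts("L1", "G1", a = 50, b = 50)
  expect_equal(assign_primary_allele(tie)$primary_allele, "allele_a")
  expect_equal(snp_secondary_fraction(50, 50), 0.5)
})
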