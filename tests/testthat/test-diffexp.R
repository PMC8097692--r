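log_matrix <- function(vals, genes, lines) {
  matrix(vals, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, lines))
}

test_that("the Welch branch reproduces the hand-computed worked example", {
  m <- log_matrix(c(1, 2, 3, 2, 4, 6), "G1", paste0("L", 1:6))
  de <- run_de(m, paste0("L", 1:3), paste0("L", 4:6),
               de_config(test = "welch", min_obs_per_group = 2),
               transform = "none")
  expect_equal(de$log2_fc, -2)
  expect_equal(de$t_stat, -2 / sqrt(5 / 3), tolerance = 1e-9)   # -1.549193
  expect_equal(de$df, 50 / 17, tolerance = 1e-9)                # 2.941176
  expect_equal(de$p_value, 0.2208808405, tolerance = 1e-9)
})

test_that("exact two-fold groups give a unit log2 fold change", {
  lines <- paste0("L", 1:8)
  set.seed(1)
  high <- matrix(2^rnorm(40, 5), 10, 4)
  m <- cbind(2 * high, high)
  dimnames(m) <- list(paste0("G", 1:10), lines)
  attr(m, "layer") <- "protein_copies"
  de <- run_de(m, lines[1:4], lines[5:8])
  expect_equal(de$log2_fc, rep(1, 10), tolerance = 1e-12)
})

test_that("identical groups yield zero fold changes and no discoveries", {
  lines <- paste0("L", 1:6)
  base <- matrix(2^rnorm(60, 5), 20, 3)
  m <- cbind(base, base)
  dimnames(m) <- list(paste0("G", 1:20), lines)
  attr(m, "layer") <- "rna_tpm"
  de <- run_de(m, lines[1:3], lines[4:6])
  expect_equal(de$log2_fc, rep(0, 20))
  expect_equal(sum(de$direction != "ns"), 0)
})

test_that("swapping group labels negates fold changes, p unchanged", {
  set.seed(5)
  m <- matrix(rnorm(120, 8), 12, 10,
              dimnames = list(paste0("G", 1:12), paste0("L", 1:10)))
  for (test in c("moderated_t", "welch")) {
    cfg <- de_config(test = test)
    a <- run_de(m, paste0("L", 1:5), paste0("L", 6:10), cfg,
                transform = "none")
    b <- run_de(m, paste0("L", 6:10), paste0("L", 1:5), cfg,
                transform = "none")
    expect_equal(a$log2_fc, -b$log2_fc)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("genes under the observation minimum carry NA statistics", {
  m <- log_matrix(c(1, 2, NA, 2, 4, 6,
                    1, 2, 3, 2, 4, 6), c("G1", "G2"), paste0("L", 1:6))
  de <- run_de(m, paste0("L", 1:3), paste0("L", 4:6),
               de_config(test = "welch"), transform = "none")
  expect_true(is.na(de$p_value[de$gene_id == "G1"]))
  expect_false(is.na(de$p_value[de$gene_id == "G2"]))
  expect_equal(de$direction[de$gene_id == "G1"], "ns")
})

test_that("the moderated t recovers the ordinary t as the prior df vanishes", {
  set.seed(9)
  x1 <- matrix(rnorm(50, 5), 10, 5)
  x2 <- matrix(rnorm(50, 6), 10, 5)
  mod0 <- xcierosion:::moderated_t_stats(x1, x2, prior_df = 0)
  welch <- xcierosion:::welch_t_stats(x1, x2)
  # on equal group sizes the Welch and pooled t statistics coincide
  expect_equal(mod0$t, welch$t, tolerance = 1e-6)
})

test_that("the moderated t agrees with limma's empirical Bayes fit", {
  set.seed(17)
  n1 <- 6; n2 <- 5
  sds <- exp(rnorm(200, log(0.5), 0.5))  # heteroscedastic genes
  x1 <- matrix(rnorm(200 * n1, 8, sds), 200, n1)
  x2 <- matrix(rnorm(200 * n2, 8, sds), 200, n2)
  x2[1:20, ] <- x2[1:20, ] + 1
  st <- xcierosion:::moderated_t_stats(x1, x2)

  design <- cbind(1, c(rep(1, n1), rep(0, n2)))
  fit <- limma::eBayes(limma::lmFit(cbind(x1, x2), design))
  expect_equal(st$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(st$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(st$df_prior, fit$df.prior, tolerance = 1e-4)
})

test_that("q-values implement BH and Storey with the expected properties", {
  expect_equal(as.numeric(qvalues(rep(1, 5), "bh")), rep(1, 5))
  expect_equal(as.numeric(qvalues(rep(1, 5), "storey")), rep(1, 5))
  # hand BH step-up: all q = 0.04
  expect_equal(as.numeric(qvalues(c(0.01, 0.02, 0.03, 0.04), "bh")),
               rep(0.04, 4))
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")

  set.seed(3)
  p <- c(runif(400), runif(100, 0, 1e-3))
  qs <- qvalues(p, "storey")
  qb <- qvalues(p, "bh")
  expect_lte(attr(qs, "pi0"), 1)
  expect_true(all(qs <= qb + 1e-12))        # pi0 <= 1 dominance
  o <- order(p)
  expect_true(all(diff(qs[o]) >= -1e-12))   # q monotone in p
})
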