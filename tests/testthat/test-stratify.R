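xist_matrix <- function(log2_vals, line_id) {
  # TPM chosen so that log2(TPM + 0.01) equals the requested value exactly
  m <- matrix(2^log2_vals - 0.01, nrow = 1,
              dimnames = list("XIST", line_id))
  make_expr(m)
}

test_that("XIST thresholds use strict inequalities with Medium boundaries", {
  ids <- paste0("L", 1:4)
  rna <- xist_matrix(c(0.5, 3.0, 1.0, 2.75), ids)
  s <- stratify_by_xist(rna, make_sheet(ids))
  expect_equal(s$stratum, c("Low", "High", "Medium", "Medium"))
})

test_that("stratification errors on a missing XIST row, excludes males", {
  ids <- paste0("L", 1:3)
  m <- make_expr(matrix(1, 1, 3, dimnames = list("GAPDH", ids)))
  expect_error(stratify_by_xist(m, make_sheet(ids)), "XIST")
  rna <- xist_matrix(c(0, 0, 5), ids)
  s <- stratify_by_xist(rna, make_sheet(ids, donor_sex = c("female", "male",
                                                           "female")))
  expect_equal(nrow(s), 2)
  expect_false("L2" %in% s$line_id)
})

test_that("strata partition all female lines", {
  b <- generate_cohort(small_config(seed = 9))
  s <- stratify_by_xist(b$rna, b$sample_sheet)
  expect_equal(nrow(s), sum(b$sample_sheet$donor_sex == "female"))
  expect_equal(sum(stratum_percentages(s)$n), nrow(s))
})

test_that("plex capping leaves plexes at or under the cap untouched", {
  ids <- paste0("L", 1:3)
  copies <- matrix(runif(30), 10, 3, dimnames = list(paste0("P", 1:10), ids))
  kept <- cap_plex_replicates(ids, copies, make_sheet(ids))
  expect_equal(kept, sort(ids))
})

test_that("identical profiles are capped deterministically to the max", {
  ids <- paste0("L", 1:5)
  prof <- runif(10, 1, 100)
  copies <- matrix(rep(prof, 5), 10, 5,
                   dimnames = list(paste0("P", 1:10), ids))
  kept <- cap_plex_replicates(ids, copies, make_sheet(ids))
  expect_length(kept, 4)
  expect_identical(kept, cap_plex_replicates(ids, copies, make_sheet(ids)))
})

test_that("capping retains cluster medoids, matching a brute-force search", {
  set.seed(31)
  # 6 lines in one plex forming 4 well-separated clusters {3,1,1,1}
  ids <- paste0("L", 1:6)
  centers <- matrix(rnorm(4 * 40, sd = 4), nrow = 40)
  assign <- c(1, 1, 1, 2, 3, 4)
  lp <- centers[, assign] + matrix(rnorm(40 * 6, sd = 0.05), 40)
  copies <- 10^lp
  dimnames(copies) <- list(paste0("P", 1:40), ids)
  kept <- cap_plex_replicates(ids, copies, make_sheet(ids))
  expect_length(kept, 4)
  # brute-force: the {3}-cluster's medoid by total correlation distance
  d <- as.matrix(as.dist(1 - cor(log10(copies))))
  trio <- ids[assign == 1]
  medoid <- trio[which.min(colSums(d[trio, trio]))]
  expect_setequal(kept, c(medoid, ids[assign != 1]))
  # idempotent and never increasing
  expect_identical(cap_plex_replicates(kept, copies, make_sheet(ids)), kept)
})

test_that("lines without protein data are dropped with a warning", {
  ids <- paste0("L", 1:3)
  copies <- matrix(1, 5, 2, dimnames = list(paste0("P", 1:5), ids[1:2]))
  expect_warning(kept <- cap_plex_replicates(ids, copies, make_sheet(ids)),
                 "without protein data")
  expect_equal(kept, c("L1", "L2"))
})

test_that("the study-shaped cohort reports 40.5/12.2/47.3 percent strata", {
  ids <- sprintf("L%02d", 1:74)
  vals <- c(rep(0.5, 30), rep(2, 9), rep(3.5, 35))
  s <- stratify_by_xist(xist_matrix(vals, ids), make_sheet(ids))
  pct <- stratum_percentages(s)
  expect_equal(pct$pct[pct$stratum == "Low"], 40.5)
  expect_equal(pct$pct[pct$stratum == "Medium"], 12.2)
  expect_equal(pct$pct[pct$stratum == "High"], 47.3)
})
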