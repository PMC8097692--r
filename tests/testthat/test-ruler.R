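test_that("QC flags and the peptide filter are applied in order", {
  I <- matrix(1, 5, 1, dimnames = list(NULL, "L1"))
  pg <- make_pg(paste0("P", 1:5), mw_da = rep(1e4, 5), intensity = I,
                rup = c(5, 5, 5, 2, 3),
                contaminant = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                reverse = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                only_site = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  kept <- filter_protein_groups(pg)
  expect_equal(kept$info$accessions, "P5")  # RUP exactly 3 is retained
  empty <- filter_protein_groups(make_pg(character(0), numeric(0),
                                         matrix(0, 0, 1,
                                                dimnames = list(NULL, "L1"))))
  expect_equal(nrow(empty$info), 0)
})

hist_anno <- function() {
  make_anno(c("H4", "B"), c("6", "1"), cytoband = c("6p22", "1q11"),
            protein_accession = c("PH", "PB"),
            histone = c(TRUE, FALSE))
}

test_that("the ruler anchors each line's histone mass to the DNA mass", {
  I <- matrix(c(100, 50), 2, 1, dimnames = list(NULL, "L1"))
  pg <- make_pg(c("PH", "PB"), mw_da = c(11367, 5000), intensity = I)
  copies <- ruler_copy_numbers(pg, hist_anno())
  # sole histone: its per-cell mass is exactly the configured 6.5 pg
  hist_mass <- copies["PH", 1] * 11367 / 6.02214076e23 * 1e12
  expect_equal(hist_mass, 6.5, tolerance = 1e-12)
  # hand arithmetic: mass_B = 6.5 * 50/100 = 3.25 pg; over 5000 Da
  expect_equal(copies["PB", 1], 3.25e-12 * 6.02214076e23 / 5000,
               tolerance = 1e-12)
  expect_equal(copies["PB", 1], 3.9144e8, tolerance = 1e-4)
})

test_that("copies are invariant to per-line intensity rescaling", {
  I <- matrix(c(100, 50, 30, 200, 80, 10), 3, 2,
              dimnames = list(NULL, c("L1", "L2")))
  pg1 <- make_pg(c("PH", "PB", "PC"), mw_da = c(11367, 5000, 8e4),
                 intensity = I)
  I2 <- I; I2[, 1] <- I2[, 1] * 10
  pg2 <- make_pg(c("PH", "PB", "PC"), mw_da = c(11367, 5000, 8e4),
                 intensity = I2)
  anno <- make_anno(c("H4", "B", "C"), c("6", "1", "2"),
                    cytoband = c("6p22", "1q11", "2q11"),
                    protein_accession = c("PH", "PB", "PC"),
                    histone = c(TRUE, FALSE, FALSE))
  expect_equal(ruler_copy_numbers(pg1, anno), ruler_copy_numbers(pg2, anno))
})

test_that("a line with no histone signal is a named error", {
  I <- matrix(c(NA, 50), 2, 1, dimnames = list(NULL, "L9"))
  pg <- make_pg(c("PH", "PB"), mw_da = c(11367, 5000), intensity = I)
  expect_error(ruler_copy_numbers(pg, hist_anno()), "L9")
})

test_that("protein content is a unit-correct additive mass sum", {
  # one mole of a 1-Da protein weighs one gram = 1e12 pg
  copies <- matrix(6.02214076e23, 1, 1, dimnames = list("PA", "L1"))
  expect_equal(unname(protein_content_pg(copies, c(PA = 1))), 1e12)

  m <- matrix(c(1e6, 2e6, 3e6, 4e5, 5e5, 6e5), 3, 2,
              dimnames = list(c("PA", "PB", "PC"), c("L1", "L2")))
  mw <- c(PA = 2e4, PB = 5e4, PC = 1.25e5)
  got <- protein_content_pg(m, mw)
  # independent spreadsheet-style recomputation
  manual <- c(L1 = (1e6 * 2e4 + 2e6 * 5e4 + 3e6 * 1.25e5),
              L2 = (4e5 * 2e4 + 5e5 * 5e4 + 6e5 * 1.25e5)) /
    6.02214076e23 * 1e12
  expect_equal(got, manual)
  # additivity across disjoint protein sets
  expect_equal(protein_content_pg(m[1, , drop = FALSE], mw) +
                 protein_content_pg(m[2:3, , drop = FALSE], mw), got)
})

test_that("batch correction equalizes plex medians and is idempotent", {
  mw <- c(PA = 1e4, PB = 1e4)
  # plex B is the minority: the grand median sits at the plex-A level
  sheet <- make_sheet(paste0("L", 1:5),
                      tmt_plex = c("A", "A", "A", "B", "B"))
  base <- matrix(rep(c(1e6, 2e6), 5), 2, 5,
                 dimnames = list(c("PA", "PB"), paste0("L", 1:5)))
  # plexes already equal in median mass: all factors 1, output == input
  same <- batch_correct(base, sheet, mw)
  expect_equal(attr(same, "plex_factors"), c(A = 1, B = 1))
  expect_equal(unclass(same)[, ], base[, ])

  # plex B uniformly 2x inflated: its factor is 0.5
  infl <- base; infl[, 4:5] <- infl[, 4:5] * 2
  corr <- batch_correct(infl, sheet, mw)
  expect_equal(attr(corr, "plex_factors"), c(A = 1, B = 0.5))
  expect_equal(unclass(corr)[, ], base[, ])

  # idempotent, and within-plex ratios between proteins preserved exactly
  twice <- batch_correct(corr, sheet, mw)
  expect_equal(unclass(twice)[, ], unclass(corr)[, ])
  expect_equal(corr["PA", ] / corr["PB", ], infl["PA", ] / infl["PB", ])
})

test_that("subunit ratios divide summed copies with zero-safe handling", {
  anno <- make_anno(c("RPL1", "RPL2", "RPS1"), c("1", "2", "3"),
                    cytoband = c("1q11", "2q11", "3q11"),
                    protein_accession = c("PL1", "PL2", "PS1"),
                    ribosome_60S = c(TRUE, TRUE, FALSE),
                    ribosome_40S = c(FALSE, FALSE, TRUE))
  copies <- matrix(c(40, 60, 50, 100, 200, 100), 3, 2,
                   dimnames = list(c("PL1", "PL2", "PS1"), c("L1", "L2")))
  r <- subunit_ratio(copies, anno)
  expect_equal(unname(r), c(2, 3))
  # homogeneity: doubling the 60S doubles the ratio
  doubled <- copies; doubled[1:2, ] <- doubled[1:2, ] * 2
  expect_equal(unname(subunit_ratio(doubled, anno)), c(4, 6))
  # zero denominator -> NA with a warning
  z <- copies; z["PS1", 1] <- 0
  expect_warning(rz <- subunit_ratio(z, anno), "zero denominator")
  expect_true(is.na(rz[1]))
})

test_that("group content comparisons use median differences and Welch tests", {
  content <- c(a1 = 1, a2 = 2, a3 = 3, b1 = 2, b2 = 4, b3 = 6)
  out <- group_content_summary(content,
                               list(A = c("a1", "a2", "a3"),
                                    B = c("b1", "b2", "b3")))
  expect_equal(out$pct_difference, 100 * (2 - 4) / 4)
  # hand Welch oracle on {1,2,3} vs {2,4,6}
  expect_equal(out$t_stat, -2 / sqrt(1 / 3 + 4 / 3), tolerance = 1e-12)
  expect_equal(out$df, 50 / 17, tolerance = 1e-6)

  same <- group_content_summary(c(x1 = 1, x2 = 2, y1 = 1, y2 = 2),
                                list(A = c("x1", "x2"), B = c("y1", "y2")))
  expect_equal(same$pct_difference, 0)
  expect_equal(same$p_value, 1)

  expect_error(group_content_summary(content, list(A = "a1", B = c("b1", "b2"))),
               "fewer than 2")
})
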