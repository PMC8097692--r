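#!/usr/bin/env Rscript
# Low- vs high-XIST differential expression on both layers: moderated t with
# empirical-Bayes variance shrinkage, Storey q-values, q <= 0.05.

suppressPackageStartupMessages(library(xcierosion))

rna <- read_expression_matrix("results/cohort/rna_tpm.tsv")
copies <- read_expression_matrix("results/protein_copies.tsv",
                                 layer = "protein_copies")
strata <- read.delim("results/strata.tsv")
retained <- readLines("results/high_retained.txt")[-1]

low <- strata$line_id[strata$stratum == "Low"]
high <- strata$line_id[strata$stratum == "High"]

de_rna <- run_de(rna, low, high)
de_prot <- run_de(copies, intersect(low, colnames(copies)), retained)
write.table(de_rna, "results/de_rna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(de_prot, "results/de_protein.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (nm in c("rna", "protein")) {
  de <- if (nm == "rna") de_rna else de_prot
  cat(sprintf("%s layer: %d genes tested, %d up, %d down at q <= 0.05 (pi0 = %.2f)\n",
              nm, sum(!is.na(de$p_value)), sum(de$direction == "up"),
              sum(de$direction == "down"), attr(de, "pi0")))
}
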