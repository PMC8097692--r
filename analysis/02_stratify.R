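#!/usr/bin/env Rscript
# Stratify female lines by XIST RNA (log2 TPM < 1 -> Low, > 2.75 -> High,
# otherwise Medium) and report the stratum split.

suppressPackageStartupMessages(library(xcierosion))

sheet <- read_sample_sheet("results/cohort/sample_sheet.tsv")
rna <- read_expression_matrix("results/cohort/rna_tpm.tsv")

strata <- stratify_by_xist(rna, sheet)
pct <- stratum_percentages(strata)
write.table(strata, "results/strata.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("XIST stratification of the female lines:\n")
print(pct, row.names = FALSE)
cat("Strata written to results/strata.tsv.\n")
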