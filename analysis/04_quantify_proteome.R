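#!/usr/bin/env Rscript
# Absolute proteome quantification: QC + peptide filtering, histone
# proteomic-ruler copy numbers, TMT plex batch correction, per-cell protein
# content, and the High-XIST plex cap.

suppressPackageStartupMessages(library(xcierosion))

sheet <- read_sample_sheet("results/cohort/sample_sheet.tsv")
anno <- read_annotation("results/cohort/annotation.tsv")
pg <- read_protein_groups("results/cohort/protein_groups.tsv", sheet)
strata <- read.delim("results/strata.tsv")

filtered <- filter_protein_groups(pg)
cat(sprintf("%d of %d protein groups pass QC flags and RUP >= 3.\n",
            nrow(filtered$info), nrow(pg$info)))

copies <- batch_correct(ruler_copy_numbers(filtered, anno), sheet)
factors <- attr(copies, "plex_factors")
cat("Plex batch factors applied:\n"); print(round(factors, 3))

high <- strata$line_id[strata$stratum == "High"]
retained <- cap_plex_replicates(high, copies, sheet)
cat(sprintf("High-XIST lines retained after the per-plex cap: %d of %d.\n",
            length(retained), length(high)))

content <- protein_content_pg(copies)
groups <- list(low_xist = strata$line_id[strata$stratum == "Low"],
               high_xist = retained,
               male = sheet$line_id[sheet$donor_sex == "male"])
summ <- group_content_summary(content, groups)
cat("Protein content comparisons (percent difference of medians, Welch p):\n")
print(summ, row.names = FALSE, digits = 3)

ratio <- subunit_ratio(copies, anno)
em <- copies; attr(em, "layer") <- "protein_copies"
write_table(em, "results/protein_copies.tsv")
write.table(data.frame(line_id = names(content), content_pg = content,
                       ratio_60s_40s = ratio[names(content)]),
            "results/protein_content.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(c("line_id", retained), "results/high_retained.txt")
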