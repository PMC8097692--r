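#!/usr/bin/env Rscript
# Test whether proteins increased at the protein level without an RNA
# increase are enriched for high abundance / high peptide support, against
# hypergeometric and resampling nulls (10,000 draws here).

suppressPackageStartupMessages(library(xcierosion))

sheet <- read_sample_sheet("results/cohort/sample_sheet.tsv")
anno <- read_annotation("results/cohort/annotation.tsv")
pg <- filter_protein_groups(
  read_protein_groups("results/cohort/protein_groups.tsv", sheet))
copies <- read_expression_matrix("results/protein_copies.tsv",
                                 layer = "protein_copies")
de_rna <- read.delim("results/de_rna.tsv")
de_prot <- read.delim("results/de_protein.tsv")

gene_of <- anno$gene_id[match(de_prot$gene_id, anno$protein_accession)]
rna_dir <- de_rna$direction[match(gene_of, de_rna$gene_id)]
both <- !is.na(de_prot$log2_fc) & !is.na(rna_dir)
universe <- de_prot$gene_id[both]
subset <- de_prot$gene_id[both & de_prot$direction == "up" & rna_dir != "up"]
cat(sprintf("Universe: %d proteins detected in both layers; subset: %d\n",
            length(universe), length(subset)))
cat("(protein-increased without an RNA increase).\n")

med_copies <- apply(copies[universe, , drop = FALSE], 1, median, na.rm = TRUE)
cfg <- enrichment_config(n_iterations = 10000, seed = 1)
print(enrich_subset(med_copies, subset, cfg))
rup <- setNames(pg$info$razor_unique_peptides, primary_accession(pg))
print(enrich_subset(rup[universe], subset, cfg))
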