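# Fixture builders shared across the test files. Everything is constructed
# in code; no fixture files are stored.

write_tsv_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

make_sheet <- function(line_id, donor_sex = rep("female", length(line_id)),
                       tmt_plex = rep("PT01", length(line_id)),
                       donor_id = paste0("D", seq_along(line_id))) {
  df <- data.frame(line_id = line_id, donor_sex = donor_sex,
                   tmt_plex = tmt_plex, donor_id = donor_id,
                   stringsAsFactors = FALSE)
  class(df) <- c("xci_sample_sheet", "data.frame")
  df
}

make_counts <- function(line_id, gene_id, a, b,
                        contig = "X",
                        position = seq_along(a) * 100) {
  xcierosion:::new_allele_counts(data.frame(
    line_id = line_id, gene_id = gene_id, contig = contig,
    position = position, allele_a_count = a, allele_b_count = b,
    stringsAsFactors = FALSE))
}

make_anno <- function(gene_id, chromosome, cytoband = paste0(chromosome, "q11"),
                      protein_accession = paste0("P", seq_along(gene_id)),
                      ribosome_60S = FALSE, ribosome_40S = FALSE,
                      ribosome_biogenesis = FALSE, histone = FALSE) {
  xcierosion:::new_annotation(data.frame(
    gene_id = gene_id, protein_accession = protein_accession,
    chromosome = chromosome, cytoband = cytoband,
    ribosome_60S = ribosome_60S, ribosome_40S = ribosome_40S,
    ribosome_biogenesis = ribosome_biogenesis, histone = histone,
    stringsAsFactors = FALSE))
}

make_pg <- function(accessions, mw_da, intensity, gene_name = accessions,
                    rup = rep(10, length(accessions)),
                    contaminant = FALSE, reverse = FALSE, only_site = FALSE) {
  n <- length(accessions)
  info <- data.frame(
    accessions = accessions, gene_name = gene_name, mw_da = mw_da,
    razor_unique_peptides = rup,
    is_contaminant = rep_len(contaminant, n),
    is_reverse = rep_len(reverse, n),
    is_only_site = rep_len(only_site, n), stringsAsFactors = FALSE)
  rownames(intensity) <- accessions
  xcierosion:::new_protein_groups(info, intensity)
}

make_expr <- function(m, layer = "rna_tpm") {
  xcierosion:::new_expression_matrix(m, layer)
}

# A small but complete cohort configuration used where full study scale is
# not needed; keeps per-test runtime low.
small_config <- function(...) {
  cohort_config(n_female_low = 8, n_female_high = 8, n_female_medium = 3,
                n_male = 5, n_genes_autosome = 120, n_genes_x = 30,
                n_histones = 8, ...)
}
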