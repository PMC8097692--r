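Package: xcierosion
Title: X-Inactivation Erosion Analysis for Female iPSC Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies erosion of X-chromosome inactivation (XCI) across female
    induced pluripotent stem cell (iPSC) lines from paired bulk RNA-seq and
    isobaric-label (TMT) proteomics. Stratifies lines by XIST RNA expression,
    measures biallelic expression from heterozygous SNP read counts
    (secondary-allele fractions), estimates absolute protein copy numbers per
    cell with the histone proteomic ruler, corrects TMT plex batch effects,
    performs moderated-t / Welch differential expression with Storey q-value
    FDR, aggregates fold changes over cytobands and chromosomes, computes
    per-cell protein content and 60S/40S ribosome stoichiometry, and tests
    enrichment with hypergeometric and resampling nulls. Includes a synthetic
    cohort generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
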