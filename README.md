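# xcierosion

Quantitative analysis of **X-chromosome inactivation (XCI) erosion** in
female human iPSC lines from paired bulk RNA-seq and TMT proteomics.

Female cells silence one X chromosome via the long non-coding RNA XIST. In
culture, female iPSC lines progressively lose this silencing: XIST
expression collapses, silenced X-linked alleles reactivate (biallelic
expression), and — strikingly — the eroded lines carry more protein per
cell genome-wide, concentrated in the large (60S) ribosomal subunit,
without a matching mRNA shift. This package implements the full analysis
chain for such cohorts, plus a synthetic cohort generator with known
injected effects so that every stage is testable end to end.

## What it computes

| Stage | Statistic |
|---|---|
| `stratify_by_xist` | Low / Medium / High XIST strata: log2(TPM+0.01) < 1, 1–2.75, > 2.75 |
| `gene_ase_fraction`, `aggregate_ase` | folded secondary-allele fraction `min(a,b)/(a+b)` per SNP (depth ≥ 20), averaged per gene / band / chromosome |
| `ruler_copy_numbers` | histone proteomic ruler: `copies = I · m_DNA · N_A / (MW · Σ_hist I)`, m_DNA = 6.5 pg |
| `batch_correct` | per-plex multiplicative equalization of median per-line protein mass |
| `protein_content_pg`, `subunit_ratio` | per-cell protein mass (pg); 60S/40S summed-copy ratio |
| `run_de`, `qvalues` | moderated t (empirical-Bayes variance shrinkage) or Welch; Storey q-values, q ≤ 0.05 |
| `summarize_by_chromosome`, `band_summary` | median log2 FC, SEM, up/down %, RNA-vs-protein FC correlation per chromosome / cytoband |
| `hypergeom_sf`, `resample_null` | enrichment of a protein subset above the 75th abundance/peptide percentile, analytic + resampling null |
| `generate_cohort`, `generate_null_cohort` | synthetic study-shaped cohort (74 female + 46 male lines) with injected erosion effects and a truth record |

Inputs are plain TSV: a MaxQuant-style `proteinGroups.txt`, a gene × line
TPM matrix, heterozygous-SNP allele counts, a gene annotation (chromosome,
cytoband, functional sets), and a sample sheet. See `?read_protein_groups`
and friends for the exact schemas.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort (`Rscript analysis/01_simulate_cohort.R`, then `02` … `08`).
Output of the first stages:

```
XIST stratification of the female lines:
 stratum  n  pct
     Low 30 40.5
  Medium  9 12.2
    High 35 47.3

Median X-chromosome secondary-allele fraction by stratum:
  High    Low Medium
0.0049 0.2263 0.0051
High-XIST lines express 99.5% of X-linked reads from the primary allele;
low-XIST lines only 77.4% - the biallelic signature of XCI erosion.

Protein content comparisons (percent difference of medians, Welch p):
   group_a   group_b median_a median_b pct_difference t_stat   df  p_value
  low_xist high_xist      230      201         14.400 23.115 46.0 5.89e-27
  low_xist      male      230      201         14.586 24.287 41.0 5.91e-26
 high_xist      male      201      201          0.162  0.288 70.5 7.74e-01
```

Reading: 40.5% of the 74 female lines have lost XIST (Low); those lines
show biallelic X-linked expression (22.6% of reads from the secondary
allele, versus 0.5% when XCI is intact) and carry ~14% more protein per
cell than High-XIST lines, while High-XIST females and males are
indistinguishable — the injected erosion effects, recovered by the
pipeline. `analysis/06_genome_summary.R` then shows the X-specific
RNA-protein fold-change concordance (r ≈ 0.95 on X, ≈ 0 on autosomes), and
`analysis/08_report.R` writes the machine-readable `results/report.json`
with every headline number.

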