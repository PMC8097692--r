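---
title: "Methods: quantifying X-inactivation erosion across iPSC multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying X-inactivation erosion across iPSC multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Background

Female human cells silence one of their two X chromosomes (X-chromosome
inactivation, XCI), a state maintained by the long non-coding RNA XIST.
In cultured female iPSC lines this silencing erodes: XIST expression is
lost, silenced X-linked alleles reactivate, and the consequences reach far
beyond the X — eroded lines carry measurably more protein per cell,
disproportionately in the large ribosomal subunit, without a matching shift
in mRNA. `xcierosion` implements the complete quantitative analysis of this
phenomenon for cohorts with paired bulk RNA-seq (TPM) and multiplexed TMT
proteomics (MaxQuant `proteinGroups.txt`-style output), together with a
synthetic cohort generator so every stage is testable end to end without
access to the original raw data.

## Stratification by XIST

Female lines are classified on `log2(TPM + 0.01)` of XIST:

* below 1: **Low XIST** (eroded),
* above 2.75: **High XIST** (XCI intact),
* otherwise **Medium**.

The inequalities are strict, so values exactly at a threshold fall to
Medium; the pseudocount of 0.01 makes zero TPM well defined and is shared
with all downstream log transforms of TPM. On a 74-line cohort split
30/9/35 this yields the 40.5% / 12.2% / 47.3% stratum percentages
(`stratum_percentages()` rounds half-up to one decimal, the convention used
for every reported percentage in the package).

Because TMT plexes are batch units, a plex contributing many High-XIST
lines would dominate the High group. `cap_plex_replicates()` limits each
plex to 4 High lines: plexes over the cap are reduced by average-linkage
hierarchical clustering on 1 − Pearson correlation of log10 copy-number
profiles, cut at k = 4, keeping each cluster's medoid (smallest summed
distance; lexicographic line-id tie-break). Linkage, distance and the
medoid rule are this package's choices — the procedure is scale-free,
deterministic and idempotent, which is what matters for a filtering step;
nothing downstream depends on the specific representative beyond batch
balance.

## Allele-specific expression

For heterozygous X-chromosome SNPs with at least 20 overlapping reads
(`min_reads_per_snp`, the depth below which folded fractions are too
granular to be informative), the per-SNP statistic is the folded
secondary-allele fraction

$$f = \frac{\min(a, b)}{a + b} \in [0, 0.5],$$

where $a, b$ are the two allele read counts. Gene-level values are
unweighted means of per-SNP fractions; chromosome- and band-level values
pool all passing SNPs in the region directly (a mean over SNPs, not over
gene means), with `snp_pooling = "gene_mean"` available as the alternative
since the distinction is not determined by the procedure's verbal
description. Fractions are folded per SNP rather than phased across SNPs —
no phasing information is assumed. The primary allele of a gene is the one
with the larger summed count over passing SNPs; ties go to `allele_a`
(the fraction statistic is unaffected by this tie-break). Intact-XCI lines
sit near $f \approx 0.005$ (99.5% of reads from the primary allele);
eroded lines near $f \approx 0.226$.

## Proteomic ruler and batch correction

Reporter intensities are converted to absolute copies per cell by anchoring
each line's total histone signal to the DNA mass of a diploid human cell
(6.5 pg, configurable):

$$\mathrm{copies}_{ij} = \frac{I_{ij} \cdot m_{\mathrm{DNA}} \cdot N_A}
{\mathrm{MW}_i \cdot \sum_{h \in \mathrm{histones}} I_{hj}}.$$

Two exact invariants follow and are unit-tested: copies are invariant to
any per-line rescaling of intensities, and each line's summed histone mass
equals $m_{\mathrm{DNA}}$ identically. Protein groups enter quantification
only if they carry no QC flag (contaminant, reverse, only-by-site) and have
at least 3 razor + unique peptides. Missing intensities stay missing — a
zero would silently enter ruler sums. Which rows are histones is decided by
the annotation table's histone set, not by hard-coded accessions.

The TMT batch correction is multiplicative per plex: every line's copies
are scaled by (grand median of per-line protein mass) / (median over that
plex's lines). This estimator preserves within-plex ratios between any two
proteins exactly and is idempotent (after one pass every plex's median
equals the grand median). The specific estimator is this package's choice
of a batch correction that respects relative abundances.

Per-cell protein content is $\sum_i \mathrm{copies}_{ij}\,\mathrm{MW}_i /
N_A \times 10^{12}$ pg; group comparisons report the percent difference of
medians with a Welch two-sample t-test. Ribosome stoichiometry is the ratio
of summed 60S copies to summed 40S copies per line.

## Differential expression

`run_de()` compares Low against High XIST lines per gene on the log2 scale
(`log2(TPM + 0.01)` for RNA; `log2` of copies with missing values skipped,
never imputed, for protein). The fold change is the difference of group
means of logs — the estimand of a two-group linear model. The default test
is a moderated t with empirical-Bayes variance shrinkage: residual
variances $s_g^2$ with $d_g$ degrees of freedom receive a scaled-F prior
whose parameters $(d_0, s_0^2)$ are fitted by method of moments on
$\log s_g^2$ (matching mean and variance of the log-variances, with the
trigamma inverse obtained by Newton iteration); posterior variances
$(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ give t statistics on $d_g + d_0$
degrees of freedom. The test suite verifies this fit against limma's
`eBayes` to machine precision and checks the $d_0 \to 0$ limit (the
ordinary t, which equals the Welch statistic for equal group sizes).
Welch's t is the configured alternative and is the test used for all
targeted group comparisons (protein content, subunit ratios).

FDR control uses Storey's q-value by default: $\hat\pi_0$ from a cubic
smoothing spline of $\hat\pi_0(\lambda) = \frac{\#\{p > \lambda\}}
{m(1-\lambda)}$ over $\lambda = 0.05, \dots, 0.95$, evaluated at
$\lambda = 0.95$ and clamped to $(0, 1]$ (with $\hat\pi_0 = 1$ for fewer
than 100 p-values, where the smoother is unreliable), then step-up minima
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. Benjamini-Hochberg is
the $\pi_0 = 1$ special case. Significance is q ≤ 0.05 throughout;
genes with fewer than 3 observations in either group are reported with
missing statistics and excluded from FDR.

## Genome-level aggregation

Chromosome summaries restrict to genes detected with a fold change in both
layers, and report per chromosome and layer the median and SEM (sample
SD/√n) of fold changes, up/down counts and percentages at q ≤ 0.05, and the
Pearson correlation between the RNA and protein fold-change vectors (left
missing below 3 shared genes). Percentages round half-up to one decimal;
note that 2,383 of 8,593 is 27.73%, which rounds to 27.7. The RNA-protein
abundance correlation uses per-gene medians across lines: log2(TPM + 0.01)
against log10 copies.

## Enrichment

The subset of interest — proteins significantly increased without a
corresponding RNA increase — is tested for enrichment in high-abundance
(or high-peptide) proteins. The threshold is the 75th percentile of the
metric over the universe (proteins detected in both layers), computed with
the linear-interpolation quantile (sorted value at fractional index
$(n-1)p$), and membership uses ≥ by default with a strict `>` mode
available (the two conventions differ in how ties at the threshold count;
thresholds such as a peptide count are discrete, so the choice is stated
rather than silent). The analytic p is the hypergeometric upper tail
$P(X \ge k)$ via `phyper`; the resampling null draws uniform subsets
without replacement (100,000 iterations at full depth; smaller counts for
interactive runs) and reports the add-one estimator
$(1 + \#\{\mathrm{draws} \ge k\})/(n_{\mathrm{iter}} + 1)$, which can never
return 0. The two routes agree within Monte-Carlo error by construction,
and `hypergeom_sf` is checked against exhaustive subset enumeration for
universes up to 12.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 30/35/9 female lines in
the Low/High/Medium XIST windows plus 46 males, 10-plex TMT with
round-robin plex assignment, secondary-allele fractions 0.005 (High and
Medium) and 0.226 (Low), a mean 1.27-fold X-linked amplification applied to
both layers in eroded lines, and a 1.13-fold autosomal protein-only
amplification representing globally increased translation. Scale is a
deliberate compute choice: 3,000 autosomal + 150 X-linked genes + 20
histone anchors stand in for the full transcriptome/proteome while keeping
a full cohort generation under a second.

Model details that matter downstream:

* Allele counts are binomial per SNP around the line's injected fraction
  with Poisson depth (mean 60), which SNP-averaged gene fractions recover
  within ±0.02 at the study's scale; males are hemizygous.
* The X amplification is heterogeneous across genes (mean-one lognormal
  multiplier, SD 0.2 on the log scale, shared between RNA and protein):
  erosion does not hit all X-linked genes equally, and the shared per-gene
  fold is what produces the high RNA-protein fold-change concordance on
  the X with near-zero concordance on autosomes.
* Protein baselines are tied to RNA baselines (slope 0.35 on the
  log10-per-log2 scale, gene scatter SD 0.5, deviations clamped at ±3 SD
  so the proteome spans a realistic ~5 orders of magnitude); histones are
  fixed to exactly 6.5 pg of summed mass (so the ruler is exact up to
  noise) and their transcripts are placed on the same abundance relation,
  as histone mRNAs are among the most abundant.
* Measurement noise is lognormal with SD 0.15 (natural log) on reporter
  intensities, shrinking with peptide support — precision improves with
  the number of quantified peptides, the usual TMT behaviour and the only
  mechanism linking significance to abundance.
* Plex factors (log-SD 0.1) multiply non-histone intensities: batch
  effects shift the sampled proteome relative to the histone anchor. A
  factor applied to every row including histones would cancel exactly in
  the ruler and be unrecoverable — modelling it this way is what makes the
  downstream batch correction estimable and testable against truth.
* All randomness flows from one root seed through named substreams
  (`substream_seed`), so changing one table's recipe leaves the others'
  draws untouched.

`generate_null_cohort()` forces all folds to 1 and equalizes the
secondary fractions; across 20 seeds the pipeline finds well under 1% of
genes at q ≤ 0.05 on it.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linkage/haplotype structure and mapping bias
in allele counts; missing reporter intensities; protein-group inference
ambiguity (one accession per gene); non-multiplicative batch distortions;
cell-cycle or culture covariates. Because the injected translation factor
is uniform, essentially every autosomal protein is truly increased in
eroded lines, so the synthetic cohort reproduces the direction but not the
magnitude of the real "27.8% of proteins up" observation, and the
high-abundance enrichment of the protein-only subset is necessarily weak
when that subset is nearly the whole universe. The cohort's RNA-protein
abundance correlation (~0.8) is likewise somewhat above the ~0.6 typical
of measured data, since only one noise source separates the layers.

## Numerical conventions and degenerate inputs

Pseudocount 0.01 for all log2 TPM transforms; half-up rounding to one
decimal for reported percentages; 6-significant-digit floats in all
writers (byte-stable output); 1-based, fully-closed SNP coordinates;
ties in primary-allele assignment to `allele_a`; ties in medoid selection
lexicographic; zero 40S sums give missing ratios with a warning; lines
with no histone signal, groups under 2 lines, and empty percentile inputs
are hard errors naming the offending entity.
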