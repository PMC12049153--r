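---
title: "Meta-program discovery and tumour ecosystem analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-program discovery and tumour ecosystem analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

scMPKit implements a complete workflow for dissecting intratumoral
heterogeneity from multi-sample single-cell RNA-seq: malignant-cell
identification from inferred copy-number profiles, per-sample consensus
NMF, aggregation of recurrent programs into cross-sample
**meta-programs** (MPs), per-cell signature scoring, ligand–receptor
interaction testing, and ecosystem-level statistics (bulk deconvolution,
correlation structure, survival stratification). Every stage is
deterministic given a single global seed, and the package ships a
synthetic-data generator that plants known programs, clones,
interactions and outcomes so the whole pipeline can be validated end to
end on a laptop.

## The synthetic cohort

`generate_dataset(sim_config())` simulates a default cohort of 8 samples
× 300 cells × 2,000 genes. The design choices matter for what the
pipeline can be expected to recover:

* **Compartments.** Each cell is epithelial (55%), stromal (25%) or
  immune (20%). Each compartment has a baseline expression profile plus
  100 marker genes for the two non-epithelial compartments; stromal and
  immune cells later serve as the copy-number reference.
* **Programs with graded loadings.** Three *shared* programs (present in
  every sample) and one *private* program per sample each own a disjoint
  block of 100 genes whose loadings taper gradually from
  `loading_strength` (default 5) down toward baseline. The taper makes
  top-gene recovery a graded, realistic problem rather than an
  all-or-nothing block detection.
* **Correlated usages.** Per-cell program usages are Dirichlet draws
  coupled through a Gaussian copula; by default the first two shared
  programs are anti-correlated at −0.6, mimicking mutually exclusive
  differentiation/invasion-like states. This planted antagonism is what
  the ecosystem stage should rediscover as a negative MP score
  correlation.
* **An 8-chromosome genome.** Genes are laid out on 8 chromosomes × 250
  genes with p/q arms of 125 genes. Malignant cells (a configurable
  fraction of epithelial cells) carry 1.5× dosage on two arms. Fewer,
  longer chromosomes are used deliberately: the copy-number caller's
  default 101-gene moving average needs chromosomes at least that long,
  and the reference noise floor of the CNV score scales like
  `sqrt(2 / n_windows)`, so short chromosomes make the score gate
  unusable at this gene count.
* **Counts.** Negative-binomial counts with log-normal library sizes and
  a reserved 100-gene tail that carries planted ligand–receptor pairs
  (sender/receiver expression multiplied by a strength factor).

Ground truth (usages, spectra, gene lists, malignant labels, planted
interactions) is returned alongside the counts.

## Pipeline stages

```{r}
library(scMPKit)
run <- run_pipeline(pipeline_config(seed = 1L))
run$report$meta_programs
```

1. **QC** (`qc_filter`): gene/UMI floors and ceilings, mitochondrial and
   haemoglobin fraction gates, then a per-sample minimum cell count;
   log-CPM normalization.
2. **CNV malignancy calling** (`smooth_cnv_profile`,
   `denoise_cnv_profile`, `classify_malignant`): residuals of each cell
   against the stromal/immune reference mean, clipped at ±3, smoothed by
   a 101-gene within-chromosome moving average, median-centred per cell,
   then denoised by zeroing entries smaller than 2 reference standard
   deviations of the gene. Denoising is what keeps the CNV *score*
   (mean squared smoothed value) comparable across sequencing depths:
   without it the Poisson noise floor of shallow cells inflates their
   score and penalizes deep cells. A cell is called malignant when its
   score exceeds the reference mean + 2 SD **and** its profile
   correlates (>0.3) with the consensus of the top-scoring 5% of cells.
3. **Per-sample consensus NMF** (`consensus_factorize`, `select_k`): 20
   multiplicative-update restarts on the z-scored (negative-clipped)
   top-500 variable genes of the malignant cells; pooled unit-L1 spectra
   are outlier-filtered (nearest-neighbour distance), k-means-clustered
   in a Pearson embedding, and summarized by cluster medians; usages are
   refit by non-negative least squares. The rank is chosen by maximizing
   the consensus silhouette **stability**, with ties broken upward —
   reconstruction error declines almost linearly in k on noisy counts
   and carries little rank information, whereas stability peaks at the
   planted rank. If no rank reaches stability 0.5 the range minimum is
   returned and flagged.
4. **Meta-programs** (`filter_recurrent_programs`, `cluster_programs`):
   programs must recur within their sample (top-50-gene overlap > 0.5
   against a second consensus at a neighbouring rank), then are
   average-linkage clustered at correlation 0.3; a cluster becomes an MP
   only if it spans at least `max(ceiling(0.2 × n_samples), 3)` distinct
   samples. Each MP is summarized by the 50 largest-weight genes of its
   members' mean unit-L1 weight vector.
5. **Scoring** (`ucell_score`, `assign_state`): per-cell MP activity via
   a capped Mann–Whitney rank sum (rank cap 1,500), invariant to any
   monotone transform of a cell's expression.
6. **Ligand–receptor testing** (`permutation_test`): cluster-level
   CellPhoneDB-style statistic (minimum over complex subunits, 10%
   expressed-fraction gate, sender/receiver mean average) with add-one
   permutation p-values; one shared label shuffle per round preserves
   the cross-pair correlation structure of the null.
7. **Ecosystem** (`nnls_deconvolve`, `spearman_cor`, `kruskal_dunn`,
   `optimal_cutpoint`): state profiles deconvolve simulated bulks by
   non-negative least squares; MP score and proportion layers are
   correlated (exact small-sample Spearman p-values); bulk MP activity
   stratifies simulated survival at a maximally selected log-rank
   cutpoint (reported as anti-conservative) with a median split
   alongside.

## Validation benchmarks

The same functions that back the test suite are exported:

```{r}
benchmark_mp_recovery(seeds = 1:10)     # planted-program recovery sweep
benchmark_cnv_detection(seeds = 1:5)    # malignancy call accuracy
benchmark_lr_calibration()              # permutation-test calibration
benchmark_test_calibration()            # KW / log-rank type-I error
benchmark_deconvolution()               # NNLS recovery
```

At the default scale the sweep recovers exactly the 3 planted shared
MPs in 10/10 seeds with mean signature Jaccard ≈ 0.67 against the
planted top-50 lists, selects the planted rank K = 4 in every sample,
and reproduces the planted −0.6 usage anti-correlation as a negative MP
score correlation in ≥ 9/10 seeds.

## Problem sizes and limitations

* The default cohort (2,400 cells × 2,000 genes) runs end to end in
  under a minute on one CPU; the 10-seed recovery sweep takes ~6
  minutes.
* Cross-sample program matching degrades sharply below ~300 cells and
  ~2,000 genes per sample: per-sample NMF still finds the programs, but
  sample-specific noise in the unit-L1 weight vectors pushes
  between-sample correlations of matching programs below the 0.3
  clustering cut. Smaller problems need either more correlated features
  or a lower cut.
* The CNV caller assumes a sizeable aneuploid fraction and diploid
  stromal/immune references; its score gate degrades when chromosomes
  hold fewer genes than the smoothing window. At the synthetic scale
  (two 125-gene 1.5× arms on a 2,000-gene panel) the malignant score is
  only ~1.3–1.6× the reference threshold, so sensitivity is marginal
  (~0.88 pooled over seeds at 30% malignancy) and varies strongly with
  the random placement of reference-compartment marker genes: markers
  elevated in stromal/immune cells read as negative residuals in every
  epithelial cell, and a seed that clusters them on a gained arm cancels
  part of the dosage plateau. Real-genome gene counts give much longer
  plateaus and correspondingly better separation.
* The maximally selected cutpoint p-value is reported uncorrected and
  flagged as anti-conservative; use the median split for honest
  inference.
* The log-rank and Kruskal–Wallis p-values are asymptotic; the log-rank
  approximation is measurably anti-conservative below ~50 subjects per
  arm (see `benchmark_test_calibration`).

## Determinism

All randomness flows from one integer seed through `derive_seed`
(stable string hashing), so enabling or disabling a stage never shifts
another stage's random stream, and two runs with the same configuration
are bit-identical — the manifest records content hashes of every stage
result to make this checkable.
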