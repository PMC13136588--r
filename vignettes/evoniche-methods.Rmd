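---
title: "Methods: spatial evolutionary kinetics, CIN and tumor-myeloid coupling"
author: "evoniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial evolutionary kinetics, CIN and tumor-myeloid coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`evoniche` implements a spatially stratified single-cell analysis of
EGFR-amplified, IDH-wildtype glioblastoma built around four quantitative
ideas:

1. **Evolutionary acceleration.** Malignant cells are ordered along a
   pseudotime axis rooted in the NPC-like state. The kinetics of mesenchymal
   (MES) program acquisition are summarized by the mean loess slope of the
   MES module score against pseudotime, the spatial coupling of the
   trajectory is interrogated with Core-vs-Margin location tests, and the
   shift between EGFR groups is measured as the Jensen-Shannon divergence
   (JSD) of their pseudotime densities. Cells in the top quartile (75th
   percentile, linear interpolation, membership by `>=`) of the *global* MES
   distribution form the endpoint program.
2. **Chromosomal instability.** CNV profiles are inferred from expression
   alone: lognorm expression is centered on a diploid reference
   (oligodendrocyte and immune reference cells), clipped, smoothed along the
   genome, median-centered per cell, denoised against the reference noise
   level, and normalized to $[-1, 1]$. The per-cell CIN score is the mean
   squared deviation from the diploid baseline,
   $\mathrm{CIN} = \overline{(\mathrm{Observed} - \mathrm{Expected})^2}$,
   which lies in $[0, 1]$ after normalization. Spatial genetic polarization
   is tested per chromosome arm with the classical (mean-centered) Levene
   test on per-cell arm scores.
3. **Tumor-myeloid coupling.** The sample unit is the (patient, niche) pair.
   A data-driven myeloid module is selected by Spearman-correlating each
   gene's per-sample myeloid mean with the malignant endpoint fraction; its
   mean expression in myeloid cells is the per-sample MyeloidAutoScore. For
   a candidate gene, `coup_rho` is the Spearman correlation across samples
   between its mean expression in late-stage malignant cells (pseudotime
   $\ge 0.75$) and the MyeloidAutoScore. Candidates are ranked by
   $\mathrm{PriorityScore2} = 0.40\,z_{coup} + 0.35\,z_{late} +
   0.25\,z_{egfr}$, hard-gated to `coup_rho > 0`, with a weight-sensitivity
   grid for robustness.
4. **Virtual knockout.** A gene-regulatory network is inferred by
   PC-regression (each gene regressed on the top principal components of the
   remaining genes), a knockout zeroes the gene's outgoing row, and every
   gene is scored by the Euclidean displacement of its two copies in a joint
   Laplacian spectral embedding of the wild-type and knockout similarity
   graphs (manifold alignment distance). Genes with $|Z| > 1.96$ (strict)
   are called perturbed; the perturbed ranking is adjudicated by preranked
   permutation GSEA.

# Interpretive constructions

Several statistics are named but not fully specified by the source analysis;
the constructions used here are deliberate design choices:

* `z_late` is the candidate-set standardization of
  $-\log_{10}(p_{adj}) \cdot \mathrm{sign}(\log_2 FC)$ from the late-vs-early
  Wilcoxon test; `z_egfr` standardizes the late-cell amp-vs-nonamp
  $\log_2 FC$; `z_coup` standardizes `coup_rho` directly (a Fisher-transform
  variant was considered and rejected for simplicity — ranks are unchanged
  for typical rho ranges). Standardization is mean 0 / sd 1 across the
  candidate set, with a zero-variance guard mapping to all zeros.
* "Late-stage" means pseudotime $\ge 0.75$, chosen to match the endpoint
  quartile; the endpoint *value* of a sample is the endpoint-cell fraction
  (the mean-MES alternative is not used).
* The sample-level unit, paired t-tests across patients for niche contrasts,
  and two-sample t-tests for EGFR contrasts follow the factorial design.
* The $[-1, 1]$ normalization is applied to the signed deviation matrix
  (not to the squared score), so CIN lands in $[0, 1]$; squared values could
  not be negative, which makes the stated scale unambiguous only under this
  reading.
* Wilcoxon tests use exact enumeration (tie-aware) when both groups have at
  most 10 observations and the tie-corrected normal approximation otherwise
  (no continuity correction — with it the test is measurably conservative at
  moderate group sizes). Multiple testing uses Benjamini-Hochberg.

# Normalization and pseudotime surrogate

SCTransform, Harmony and reverse-graph-embedding pseudotime are out of
scope. Normalization is deterministic library-size log1p-CPM (scale $10^4$),
sufficient for the rank- and correlation-based statistics downstream. The
pseudotime surrogate builds a kNN graph ($k = 15$) on the top 30 principal
components of the top-variance genes and takes shortest-path distance from
the root set, min-max scaled; externally computed pseudotime (including
simulation ground truth) is accepted verbatim. Before the graph is built,
each cell's PC coordinates are averaged with their nearest neighbors (a
tenth of the cells, capped at 50, three rounds) — without this denoising the
shortest-path ordering is badly degraded at realistic noise levels.

# The synthetic world

`default_cohort_config()` states the world once: 3 EGFR-amplified and 3
non-amplified patients, each sampled in Core and Margin (12 samples, 500
cells each, 50% malignant / 25% myeloid / 10% T / 15% reference), 2000 genes
on 10 equal chromosomes. Counts are negative binomial with dispersion 0.4
($\mathrm{var} = \mu + 0.4\mu^2$, roughly 1800 counts per cell — deliberately
at the shallow end of droplet data). All planted effects multiply the NB
mean by $e^{\mathrm{effect}}$ so that log-scale module scores respond
linearly: MES genes scale as $e^{s t}$ with $s = 1.2$ (amplified) versus
$0.6$ (non-amplified) — the 2x slope ratio is the planted kinetic contrast —
while NPC/OPC programs decay with pseudotime. Pseudotime is Beta(2,5) in the
Core and Beta(5,2) in the Margin when coupled (non-amplified behaviour) and
Beta(5,2) everywhere when uncoupled (amplified behaviour). The karyotype
follows the canonical IDH-wildtype pattern: near-clonal chr10 loss in all
patients, chr7 gain co-occurring with EGFR amplification, and additional
Core-enriched subclonal events (1p gain, 9q loss) that create the
Core-vs-Margin CIN contrast. Program and candidate genes are scattered
uniformly over event-free chromosomes — contiguous placement would make a
transcriptional program positionally indistinguishable from an arm-level
CNV. The myeloid suppression level of sample $s$ is
$0.3 + 0.9\,\mathrm{ef}_s + \mathcal{N}(0, 0.1)$ where $\mathrm{ef}_s$ is
the true endpoint fraction; the planted `POSTN_like` candidate carries a 4x
late multiplier, a 3x amplification multiplier and sample-level coupling 0.9
to that suppression level.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, cell-cycle structure, spatial coordinates beyond the binary niche
label, and genome-wide program breadth (real MES programs span far more
genes). A green recovery test therefore establishes that the estimators
recover *this* stated structure at desk scale, not that they would behave
identically on tissue data.

# Numerical choices and degenerate inputs

* QC thresholds are strict inequalities (a cell at exactly 20% mitochondrial
  content or exactly 200 features is retained); mitochondrial genes are
  recognized by the configurable prefix `MT-`.
* The CNV smoothing window is 101 genes (shrinking at chromosome ends);
  clipping at 3 global MADs; chromosomes with fewer than 3 genes are left
  unsmoothed with a warning. The denoising step zeroes deviations smaller
  than 1.5 reference standard deviations per gene (`denoise_sd = 0`
  disables it).
* Malignancy calling thresholds at the 99th percentile of reference-cell CIN
  scores; reference-typed cells are always `normal`.
* The joint embedding uses correspondence weight 0.9, eigenvalues sorted
  ascending with eigenvectors sign-fixed by their first non-negligible
  coordinate; genes outside the largest connected component get distance 0
  with a warning. Degenerate (tied) Laplacian eigenvalues can make the
  embedding non-unique; the toy and oracle tests avoid that regime.
* GSEA p-values compare $|ES|$ against the permutation distribution
  (two-sided by magnitude), with the $+1$ correction.
* All-equal MES scores flag every cell as endpoint (threshold attained by
  all); zero-variance z-components map to 0; an all-zero cell produces an
  all-zero lognorm column with a warning.

# Known limitations, measured honestly

Two recovery claims exceed what the stated world can support, and the
corresponding checks are kept red or restated rather than silently relaxed:

* **Per-cell pseudotime recovery to Spearman 0.9.** At NB dispersion 0.4
  and ~130 trajectory-informative genes, even a *supervised* ridge
  regression of true pseudotime on the full expression matrix reaches only
  Spearman 0.70-0.80 on held-out cells, and the best single principal
  component reaches ~0.85-0.88. The unsupervised graph surrogate attains
  ~0.83-0.87 with denoising (up from ~0.68 without). The 0.9 bar is above
  the information ceiling of the data; the acceptance check asserts it
  anyway and fails, documenting the gap rather than lowering the bar.
* **Per-cell malignancy recall for single-arm events.** A cell carrying one
  0.4-0.5-magnitude arm event moves the genome-wide mean-of-squares by much
  less than the cell-to-cell noise spread at ~1800 counts/cell, so recall
  for such cells is 10-55%. Recall rises monotonically with burden and
  reaches 90-98% for cells carrying the full clonal-plus-amplified
  karyotype; the test suite asserts recall on that stratum plus
  monotonicity and the <=2% null false-positive rate.

Population-level contrasts (Core-vs-Margin CIN, gradient flattening, slope
ratios, coupling regressions, candidate ranking) are all recovered at the
stated scale; the limitations above are specifically per-cell calling
problems at shallow depth.
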