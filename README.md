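# evoniche

Spatially stratified single-cell analysis of EGFR-amplified, IDH-wildtype
glioblastoma: evolutionary kinetics along pseudotime, expression-inferred
chromosomal instability (CIN), tumor–myeloid coupling, candidate
prioritization, and in-silico network perturbation.

## Who this is for

Computational biologists analysing single-cell RNA-seq cohorts with a 2×2
factorial design — patients stratified by EGFR amplification status
(`EGFR_amp` / `non_EGFR_amp`) and intratumoral sampling niche (`Core` /
`Margin`) — who want a tested, reusable implementation of the following
pipeline rather than a one-off analysis script.

## The quantitative core

- **Evolutionary acceleration.** Malignant cells are ordered by a pseudotime
  rooted in the NPC-like state. The mesenchymal (MES) acquisition rate is the
  mean loess slope of the MES module score against pseudotime; the spatial
  coupling of the trajectory is tested Core-vs-Margin; the distributional
  shift between EGFR groups is the base-2 Jensen–Shannon divergence of their
  pseudotime densities. Cells in the top quartile (≥ 75th percentile) of the
  global MES score form the *endpoint program*.
- **CIN score.** CNV profiles are inferred from expression against a diploid
  reference (oligodendrocyte/immune cells): centering, clipping, positional
  smoothing, per-cell median centering, reference-noise denoising, and
  normalization to [−1, 1]. Per cell,
  `CIN = mean((Observed − Expected)²) ∈ [0, 1]`. Spatial genetic
  polarization is tested per chromosome arm with Levene's test.
- **Tumor–myeloid coupling.** Per (patient, niche) sample: the endpoint-cell
  fraction (tumor side) and the `MyeloidAutoScore` (mean expression of a
  data-driven myeloid module in myeloid cells). For a candidate gene,
  `coup_rho` is the Spearman correlation across samples between its mean
  expression in late-stage malignant cells and the MyeloidAutoScore.
- **PriorityScore2.**
  `0.40·z_coup + 0.35·z_late + 0.25·z_egfr`, hard-gated to `coup_rho > 0`,
  with a weight-sensitivity grid.
- **Virtual knockout.** A PC-regression gene-regulatory network; knockout =
  zeroing the gene's outgoing adjacency row; per-gene effect = manifold
  alignment distance between wild-type and knockout network embeddings;
  significance at |Z| > 1.96; preranked GSEA on the perturbed ranking.

A negative-binomial simulator (`generate_dataset`, `default_cohort_config`)
emulates the 6-patient × 2-niche design with planted pseudotime, arm-level
CNV events, sample-level tumor–myeloid coupling and a planted `POSTN_like`
candidate, so every stage is recovery-testable against ground truth.

## Worked example

```r
library(evoniche)

sim <- generate_dataset(default_cohort_config(seed = 2))
ds  <- log_normalize(qc_filter(sim$dataset)$dataset)
mal <- ds$cells$cell_type == "malignant"

mes <- score_module(ds, sim$truth$programs$MES, seed = 1)
ep  <- assign_endpoint_program(mes[mal])

prof  <- call_malignant(infer_cnv_profile(ds))
polar <- spatial_polarization_test(prof, malignant_mask = mal)
print(polar$cin_tests, digits = 3)
#>    egfr_status        p median_core median_margin
#> 1     EGFR_amp 2.45e-32      0.0328        0.0264
#> 2 non_EGFR_amp 1.40e-42      0.0262        0.0201

samples <- sample_summary(ds, mal, ep$flag)
module  <- suppressWarnings(select_myeloid_module(ds, samples))
samples <- myeloid_auto_score(ds, module$gene_id, samples)
reg <- endpoint_myeloid_regression(samples)
cat(sprintf("tumor-myeloid coupling: R2 = %.2f, p = %.4f\n",
            reg$overall$r_squared, reg$overall$p))
#> tumor-myeloid coupling: R2 = 0.55, p = 0.0055

ranked <- prioritize_candidates(ds, mal, sim$truth$cells$true_pseudotime[mal],
                                samples)
print(head(ranked[, c("gene_id", "coup_rho", "z_coup", "z_late", "z_egfr",
                      "priority_score2", "rank")], 3), digits = 2)
#>      gene_id coup_rho z_coup z_late z_egfr priority_score2 rank
#> 1 POSTN_like     0.66   0.93    7.5   4.59            4.15    1
#> 2      G0858     0.94   1.78    0.6   0.98            1.17    2
#> 3      G0229     0.86   1.53    0.9   0.19            0.97    3
```

Reading the output: malignant Core cells carry significantly higher CIN than
Margin cells in both EGFR groups (Wilcoxon rank-sum); the endpoint-program
fraction linearly predicts the per-sample MyeloidAutoScore (R² = 0.55 across
the 12 samples); and the planted candidate wins the hard-gated PriorityScore2
ranking on the strength of its late-state enrichment (`z_late`) and
EGFR-amplified specificity (`z_egfr`), despite competitors with higher raw
coupling.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Re-runs the installed package end to end on the default synthetic design —
simulation, QC, normalization, module scoring, endpoint calls, graph
pseudotime, loess kinetics, CNV/CIN inference with spatial polarization
tests, myeloid module selection, coupling regression, PriorityScore2 ranking
with weight sensitivity, and a virtual knockout of the top-ranked candidate —
then writes the JSON report to `--out`. All randomness derives from `--seed`.

## Command line

A thin wrapper over the exported functions ships in
`inst/scripts/evo-niche.R` (subcommands `simulate`, `qc`, `cnv`); the R API
is the primary interface.

## Further reading

`vignettes/evoniche-methods.Rmd` documents the model and its assumptions,
the interpretive constructions behind the z-components, the synthetic
world's parameters and what it does and does not emulate, numerical edge
cases, and two measured per-cell detection limits at shallow sequencing
depth.
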