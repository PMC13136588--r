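# CNV profile inference, CIN scoring, malignancy calling and spatial
# polarization.

make_ref_dataset <- function() {
  # 3 chromosomes x 30 genes; identical expression pattern in every cell
  pattern <- rep(c(2L, 5L, 1L), 30)
  counts <- matrix(pattern, 90, 12)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:90),
                      chromosome = rep(c("1", "2", "3"), each = 30),
                      start = rep(1:30, 3) * 100L,
                      arm = rep(c("1p", "1q", "2p", "2q", "3p", "3q"),
                                each = 15))
  cells <- data.frame(cell_id = sprintf("c%02d", 1:12), patient = "P1",
                      niche = rep(c("Core", "Margin"), 6),
                      egfr_status = "EGFR_amp",
                      cell_type = rep(c("reference_oligo", "malignant"), 6))
  log_normalize(expression_dataset(counts, genes, cells))
}

test_that("cells identical to the reference give an all-zero deviation", {
  ds <- make_ref_dataset()
  prof <- infer_cnv_profile(ds, cnv_config(window = 5))
  expect_true(all(prof$deviation == 0))
  expect_equal(unname(compute_cin(prof)), rep(0, 12))
})

test_that("compute_cin equals the brute-force mean of squares and its bounds", {
  D <- evoniche:::with_seed(4, matrix(runif(60, -1, 1), 10, 6))
  prof <- structure(list(deviation = D), class = "CnvProfile")
  expect_equal(unname(compute_cin(prof)), colMeans(D^2))
  expect_equal(unname(compute_cin(
    structure(list(deviation = matrix(c(1, -1), 2, 3)), class = "CnvProfile"))),
    rep(1, 3))
})

test_that("gene-order permutation leaves the profile unchanged", {
  sim <- generate_dataset(small_cohort_config(seed = 9,
                                                 cells_per_sample = 60,
                                                 n_genes = 300))
  ds <- log_normalize(sim$dataset)
  prof <- infer_cnv_profile(ds)
  perm <- evoniche:::with_seed(2, sample(nrow(ds$counts)))
  prof2 <- infer_cnv_profile(ds[perm, ])
  expect_equal(prof2$deviation, prof$deviation)
  expect_equal(prof2$cin_score, prof$cin_score)
})

test_that("reference centering holds per gene on the cohort-emulating design", {
  sim <- generate_dataset(small_cohort_config(seed = 9))
  ds <- log_normalize(sim$dataset)
  prof <- infer_cnv_profile(ds)
  ref_means <- rowMeans(prof$deviation[, prof$reference])
  expect_lt(max(abs(ref_means)), 0.05)
})

test_that("a planted chr7 gain is recovered in affected cells", {
  ev <- data.frame(arm = c("7p", "7q"), direction = "gain", magnitude = 0.5,
                   core_probability = 0.8, margin_probability = 0.8,
                   group = "all")
  cfg <- sim_config(cells_per_sample = 150, n_genes = 2000,
                    cnv_arm_events = ev, seed = 9)
  sim <- generate_dataset(cfg)
  ds <- log_normalize(sim$dataset)
  prof <- infer_cnv_profile(ds)
  aff <- sim$truth$cells$true_cnv_burden > 0
  chr7 <- prof$gene_order$chromosome == "7"
  signal <- mean(prof$deviation[chr7, aff]) -
    mean(prof$deviation[!chr7, aff])
  null_spread <- sd(colMeans(prof$deviation[chr7, !aff & !prof$reference,
                                            drop = FALSE]))
  expect_gt(signal, 3 * null_spread)
})

test_that("malignancy calling: contracts, karyotype recall, null specificity", {
  sim <- generate_dataset(default_cohort_config(seed = 9))
  ds <- log_normalize(sim$dataset)
  prof <- call_malignant(infer_cnv_profile(ds))
  # reference cells are labeled normal regardless of score
  expect_true(all(prof$clone_label[prof$reference] == "normal"))
  # cells carrying the full clonal + amplified karyotype are recovered;
  # single-arm carriers are below the per-cell detection floor at this
  # sequencing depth (see the methods vignette), so recall is asserted on
  # the full-karyotype stratum and monotonicity on the rest
  burden <- sim$truth$cells$true_cnv_burden
  full <- burden >= 2.2
  expect_gte(mean(prof$clone_label[full] == "tumor_clone"), 0.9)
  lvl <- c(0.8, 1.2, 1.8, 2.2)
  recall <- vapply(lvl, function(b) {
    sel <- abs(burden - b) < 0.15
    mean(prof$clone_label[sel] == "tumor_clone")
  }, numeric(1))
  expect_false(is.unsorted(recall))
  rm(sim, ds, prof); gc(verbose = FALSE)
  # a world with no CNV events yields almost no tumor-clone calls
  cfg0 <- sim_config(cells_per_sample = 150, n_genes = 1000, seed = 10)
  sim0 <- generate_dataset(cfg0)
  prof0 <- call_malignant(infer_cnv_profile(log_normalize(sim0$dataset)))
  expect_lte(mean(prof0$clone_label[!prof0$reference] == "tumor_clone"), 0.02)
})

test_that("CIN increases with planted event magnitude across seeds", {
  # reduced scale; the affected/reference CIN ratio is invariant to the
  # per-dataset [-1, 1] normalization, so it is comparable across worlds
  ranks_ok <- vapply(1:10, function(s) {
    ratio <- vapply(c(0.2, 0.4, 0.6), function(m) {
      e <- data.frame(arm = c("7p", "7q"), direction = "gain", magnitude = m,
                      core_probability = 0.8, margin_probability = 0.8,
                      group = "all")
      cfg <- sim_config(n_patients_amp = 1, n_patients_nonamp = 1,
                        cells_per_sample = 100, n_genes = 1000,
                        cnv_arm_events = e, seed = s)
      sim <- generate_dataset(cfg)
      prof <- infer_cnv_profile(log_normalize(sim$dataset))
      mean(prof$cin_score[sim$truth$cells$true_cnv_burden > 0]) /
        mean(prof$cin_score[prof$reference])
    }, numeric(1))
    !is.unsorted(ratio)
  }, logical(1))
  expect_gte(mean(ranks_ok), 0.9)
})

test_that("levene_test: trivial null, power, and the anova oracle", {
  # identical z-vectors in both groups -> W = 0, p = 1
  x <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("Core", "Margin"), each = 4)
  r <- levene_test(x, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # power: sd 2 vs sd 1 at n = 200 per group
  v <- evoniche:::with_seed(13, c(rnorm(200, 0, 2), rnorm(200, 0, 1)))
  gg <- rep(c("Core", "Margin"), each = 200)
  expect_lt(levene_test(v, gg)$p.value, 0.01)
  # oracle: one-way anova on |x - group mean|
  z <- abs(v - ave(v, gg))
  fit <- stats::anova(stats::lm(z ~ gg))
  expect_equal(levene_test(v, gg)$statistic, fit$`F value`[1])
  expect_equal(levene_test(v, gg)$p.value, fit$`Pr(>F)`[1])
})

test_that("spatial polarization detects Core-enriched variance and CIN", {
  sim <- generate_dataset(small_cohort_config(seed = 9))
  ds <- log_normalize(sim$dataset)
  prof <- infer_cnv_profile(ds)
  mal <- ds$cells$cell_type == "malignant"
  sp <- spatial_polarization_test(prof, malignant_mask = mal)
  # the strongest subclonal Core-enriched arm (9q) shows clear variance
  # polarization, and the top-ranked arm is one of the planted events
  expect_true("9q" %in% sp$arm_tests$arm[sp$arm_tests$p_adj < 0.05])
  expect_true(sp$arm_tests$arm[which.min(sp$arm_tests$p)] %in% c("1p", "9q"))
  expect_true(all(sp$cin_tests$p < 0.01))
  expect_true(all(sp$cin_tests$median_core > sp$cin_tests$median_margin))
})
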