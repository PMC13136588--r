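# Tumor-myeloid coupling, MyeloidAutoScore and PriorityScore2.

# small multi-sample dataset with controllable myeloid/malignant expression
make_coupling_dataset <- function(gene_vals, n_samples = 6, seed = 1) {
  # gene_vals: genes x samples matrix of NB means used for BOTH myeloid and
  # malignant cells of that sample (deterministic large counts, noise-free)
  G <- nrow(gene_vals)
  per <- 8                                   # cells per sample
  counts <- NULL
  cells <- NULL
  for (s in seq_len(n_samples)) {
    block <- matrix(rep(gene_vals[, s], per), nrow = G)
    counts <- cbind(counts, block)
    cells <- rbind(cells, data.frame(
      cell_id = sprintf("s%d_c%d", s, seq_len(per)),
      patient = sprintf("P%d", ceiling(s / 2)),
      niche = c("Core", "Margin")[(s - 1) %% 2 + 1],
      egfr_status = if (s <= n_samples / 2) "EGFR_amp" else "non_EGFR_amp",
      cell_type = rep(c("malignant", "myeloid"), each = per / 2)))
  }
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(G)),
                      chromosome = "1", start = seq_len(G), arm = "1p")
  log_normalize(expression_dataset(counts, genes, cells))
}

test_that("myeloid_auto_score equals the brute-force per-sample mean", {
  ds <- make_toy_dataset(n_genes = 20, n_cells = 40, seed = 5,
                         cell_type = rep(c("malignant", "myeloid"), 20),
                         patient = rep(c("P1", "P2"), each = 20),
                         niche = rep(rep(c("Core", "Margin"), each = 10), 2))
  flag <- rep(TRUE, sum(ds$cells$cell_type == "malignant"))
  samples <- sample_summary(ds, ds$cells$cell_type == "malignant", flag)
  module <- ds$genes$gene_id[c(2, 7, 11)]
  out <- myeloid_auto_score(ds, module, samples)
  key <- evoniche:::sample_key(ds$cells)
  L <- as.matrix(ds$lognorm)
  manual <- vapply(samples$sample_id, function(s) {
    cols <- key == s & ds$cells$cell_type == "myeloid"
    mean(rowMeans(L[c(2, 7, 11), cols, drop = FALSE]))
  }, numeric(1))
  expect_equal(out$myeloid_auto_score, unname(manual))
  # one-gene module equals that gene's sample mean over myeloid cells
  one <- myeloid_auto_score(ds, module[1], samples)
  manual1 <- vapply(samples$sample_id, function(s) {
    mean(L[2, key == s & ds$cells$cell_type == "myeloid"])
  }, numeric(1))
  expect_equal(one$myeloid_auto_score, unname(manual1))
})

test_that("a constant expression matrix scores the constant everywhere", {
  vals <- matrix(7L, 10, 6)
  ds <- make_coupling_dataset(vals)
  flag <- rep(TRUE, sum(ds$cells$cell_type == "malignant"))
  samples <- sample_summary(ds, ds$cells$cell_type == "malignant", flag)
  out <- myeloid_auto_score(ds, ds$genes$gene_id[1:4], samples)
  v <- as.numeric(ds$lognorm[1, 1])
  expect_equal(out$myeloid_auto_score, rep(v, 6))
})

test_that("spearman_rho reproduces hand-computed ranks", {
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_equal(spearman_rho(1:6, 2 * (1:6) + 3), 1)
  expect_equal(spearman_rho(1:6, -(1:6)), -1)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
})

test_that("coupling_rho correlates late-malignant means with MyeloidAutoScore", {
  # malignant (late) expression of g01 increases over samples; a myeloid
  # module gene increases in lockstep -> rho = 1; g02 decreases -> rho = -1
  vals <- matrix(10, 4, 6)
  vals[1, ] <- c(5, 10, 20, 40, 80, 160)   # candidate up
  vals[2, ] <- rev(c(5, 10, 20, 40, 80, 160))
  vals[3, ] <- c(6, 12, 24, 48, 96, 192)   # myeloid module gene
  ds <- make_coupling_dataset(vals)
  mal <- ds$cells$cell_type == "malignant"
  pt <- rep(1, sum(mal))                   # all malignant cells are late
  samples <- sample_summary(ds, mal, rep(TRUE, sum(mal)))
  samples <- myeloid_auto_score(ds, "g03", samples)
  expect_equal(coupling_rho(ds, mal, pt, samples, "g01"), 1)
  expect_equal(coupling_rho(ds, mal, pt, samples, "g02"), -1)
  # fewer than 4 usable samples errors
  expect_error(coupling_rho(ds, mal, pt, samples[1:3, ], "g01"),
               class = "evoniche_value_error")
})

test_that("select_myeloid_module keeps positively coupled genes only", {
  # endpoint_value rises across samples; g01/g03 rise with it, g02 falls,
  # g04 constant
  vals <- matrix(10, 5, 6)
  vals[1, ] <- c(5, 10, 20, 40, 80, 160)
  vals[2, ] <- rev(c(5, 10, 20, 40, 80, 160))
  vals[3, ] <- c(2, 4, 8, 16, 32, 64)
  ds <- make_coupling_dataset(vals)
  mal <- ds$cells$cell_type == "malignant"
  samples <- sample_summary(ds, mal, rep(TRUE, sum(mal)))
  samples$endpoint_value <- seq(0.1, 0.6, 0.1)
  mod <- suppressWarnings(
    select_myeloid_module(ds, samples, rho_threshold = 0.9, min_genes = 2))
  expect_true(all(c("g01", "g03") %in% mod$gene_id))
  expect_false("g02" %in% mod$gene_id)
  expect_false("g04" %in% mod$gene_id)   # constant -> undefined rho
})

test_that("late_up_candidates finds the planted candidate with positive z_late", {
  sim <- generate_dataset(small_cohort_config(seed = 2))
  ds <- log_normalize(sim$dataset)
  mal <- ds$cells$cell_type == "malignant"
  pt <- sim$truth$cells$true_pseudotime[mal]
  cand <- late_up_candidates(ds, mal, pt)
  expect_true("POSTN_like" %in% cand$gene_id)
  expect_gt(cand$z_late[cand$gene_id == "POSTN_like"], 0)
  # ligand restriction: disjoint list empties the table with a warning
  expect_warning(out <- late_up_candidates(ds, mal, pt,
                                           ligand_list = "not_a_gene"),
                 "no candidates")
  expect_equal(nrow(out), 0)
  # empty strata error
  expect_error(late_up_candidates(ds, mal, rep(0.5, sum(mal))),
               class = "evoniche_empty_group")
})

test_that("z_egfr_specificity standardizes and guards zero variance", {
  vals <- matrix(10, 3, 6)
  vals[1, 1:3] <- 40                      # g01 higher in amp samples
  ds <- make_coupling_dataset(vals)
  mal <- ds$cells$cell_type == "malignant"
  pt <- rep(1, sum(mal))
  z <- z_egfr_specificity(ds, mal, pt, c("g01", "g02", "g03"))
  expect_gt(z$z_egfr[z$gene_id == "g01"], 0)
  # genes with identical specificity collapse to z = 0 (zero-variance guard)
  z0 <- z_egfr_specificity(ds, mal, pt, c("g02", "g03"))
  expect_equal(z0$z_egfr, c(0, 0))
  # a fully uniform dataset has zero raw specificity for every gene
  ds0 <- make_coupling_dataset(matrix(10, 3, 6))
  z00 <- z_egfr_specificity(ds0, ds0$cells$cell_type == "malignant",
                            rep(1, sum(ds0$cells$cell_type == "malignant")),
                            c("g01", "g02"))
  expect_equal(z00$egfr_log2fc, c(0, 0))
})

test_that("priority_score2 is the exact weighted sum with a hard gate", {
  cand <- data.frame(gene_id = c("a", "b", "c", "d"),
                     coup_rho = c(0.9, 0.5, -0.2, 0),
                     z_coup = c(1, 1, 5, 5),
                     z_late = c(1, 0, 5, 5),
                     z_egfr = c(1, 0, 5, 5))
  out <- priority_score2(cand)
  expect_equal(out$priority_score2[out$gene_id == "a"], 1.00, tolerance = 1e-12)
  expect_equal(out$priority_score2[out$gene_id == "b"], 0.40, tolerance = 1e-12)
  # coup_rho <= 0 is excluded from ranking (strict gate)
  expect_false(out$gated[out$gene_id == "c"])
  expect_false(out$gated[out$gene_id == "d"])
  expect_true(all(is.na(out$rank[!out$gated])))
  expect_equal(out$gene_id[out$rank == 1][1], "a")
  expect_error(priority_score2(cand, c(0, 0, 0)),
               class = "evoniche_config_error")
  expect_error(priority_score2(cand, c(-0.1, 0.6, 0.5)),
               class = "evoniche_config_error")
})

test_that("ranking with weights (1,0,0) equals the z_coup ordering", {
  cand <- evoniche:::with_seed(3, data.frame(
    gene_id = sprintf("g%02d", 1:12),
    coup_rho = runif(12, 0.05, 0.95),
    z_coup = rnorm(12), z_late = rnorm(12), z_egfr = rnorm(12)))
  out <- priority_score2(cand, c(1, 0, 0))
  expect_equal(out$gene_id[order(out$rank)],
               cand$gene_id[order(-cand$z_coup)])
  # candidate order never changes scores or the gated set
  perm <- evoniche:::with_seed(4, sample(12))
  out2 <- priority_score2(cand[perm, ], c(1, 0, 0))
  expect_equal(out2[order(out2$gene_id), ], out[order(out$gene_id), ],
               ignore_attr = TRUE)
})

test_that("weight sensitivity: dominance and single-candidate degeneracy", {
  one <- data.frame(gene_id = "only", coup_rho = 0.5, z_coup = 1,
                    z_late = 1, z_egfr = 1)
  sens1 <- weight_sensitivity(one)
  expect_equal(sens1$min_rank, 1)
  expect_equal(sens1$max_rank, 1)
  expect_equal(sens1$top_tier_freq, 1)
  many <- data.frame(gene_id = c("dom", "x", "y"),
                     coup_rho = c(0.9, 0.5, 0.4),
                     z_coup = c(2, 1, 0), z_late = c(2, 0, 1),
                     z_egfr = c(2, 1, 1))
  sens <- weight_sensitivity(many)
  expect_equal(sens$max_rank[sens$gene_id == "dom"], 1)
  expect_error(weight_sensitivity(many, matrix(c(0.4, 0.35, 0.25), 1)),
               class = "evoniche_config_error")
})

test_that("endpoint_myeloid_regression recovers an exact line", {
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        patient = paste0("P", 1:6),
                        niche = rep(c("Core", "Margin"), 3),
                        egfr_status = rep(c("EGFR_amp", "non_EGFR_amp"),
                                          each = 3),
                        endpoint_value = seq(0.1, 0.6, 0.1))
  samples$myeloid_auto_score <- 2 * samples$endpoint_value + 1
  fit <- suppressWarnings(endpoint_myeloid_regression(samples))
  expect_equal(fit$overall$slope, 2)
  expect_equal(fit$overall$r_squared, 1)
  samples$endpoint_value <- 0.3
  expect_error(endpoint_myeloid_regression(samples),
               class = "evoniche_value_error")
})
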