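# Programmatic fixtures: small ExpressionDatasets built in code.

# iid negative-binomial toy dataset with a single-sample design
make_toy_dataset <- function(n_genes = 50, n_cells = 100, mu = 2, size = 3,
                             seed = 7, cell_type = "malignant",
                             patient = "P1", niche = "Core",
                             egfr_status = "EGFR_amp", normalize = TRUE) {
  counts <- evoniche:::with_seed(seed, {
    matrix(stats::rnbinom(n_genes * n_cells, mu = mu, size = size),
           nrow = n_genes)
  })
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      chromosome = "1",
                      start = seq_len(n_genes) * 1000L,
                      arm = "1p",
                      stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)),
                      patient = rep_len(patient, n_cells),
                      niche = rep_len(niche, n_cells),
                      egfr_status = rep_len(egfr_status, n_cells),
                      cell_type = rep_len(cell_type, n_cells),
                      stringsAsFactors = FALSE)
  ds <- expression_dataset(counts, genes, cells)
  if (normalize) ds <- log_normalize(ds)
  ds
}

# reduced cohort-emulating configuration for fast recovery tests (12-sample design
# preserved; cells, genes and program sizes scaled down for runtime)
small_cohort_config <- function(seed = 1, cells_per_sample = 150,
                                   n_genes = 600) {
  cfg <- default_cohort_config(seed = seed)
  sim_config(cells_per_sample = cells_per_sample, n_genes = n_genes,
             program_gene_counts = c(NPC = 25, OPC = 15, AC = 15, MES = 25,
                                     myeloid_suppression = 15,
                                     cytotoxicity = 10),
             cnv_arm_events = cfg$cnv_arm_events,
             planted_candidates = cfg$planted_candidates,
             seed = seed)
}

# independent exhaustive two-sided rank-sum p-value by enumerating all
# group assignments (oracle for rank_sum_test / wilcoxon_de)
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  sums <- apply(utils::combn(length(r), nx), 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
}
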