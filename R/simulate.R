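# Synthetic-data generator: negative-binomial counts over a 2x2 factorial
# design (EGFR_amp/non_EGFR_amp patients x Core/Margin niches) with planted
# pseudotime, arm-level CNV events, a myeloid suppression module coupled to
# the malignant endpoint program at the sample level, and planted candidate
# genes. Every planted quantity is echoed in a GroundTruth object that the
# pipeline itself never consumes.
#
# Noise model: counts ~ NB(mu, size = 1/noise_dispersion), i.e.
# var = mu + noise_dispersion * mu^2. All planted effects act multiplicatively
# on mu as exp(effect), so log-scale readouts (module scores) are linear in
# the planted effect sizes.

#' Simulation configuration
#'
#' @param n_patients_amp,n_patients_nonamp patients per EGFR group.
#' @param cells_per_sample cells per (patient, niche) sample.
#' @param fractions named fractions (`malignant`, `myeloid`, `t_cell`,
#'   `reference`) summing to 1; reference cells are split evenly between
#'   oligodendrocyte and immune reference types.
#' @param n_genes total genes, laid out on `n_chromosomes` chromosomes of
#'   equal size with p/q arms of half a chromosome each.
#' @param n_chromosomes chromosomes in the synthetic genome.
#' @param program_gene_counts named integer vector of genes per expression
#'   program (`NPC`, `OPC`, `AC`, `MES`, `myeloid_suppression`,
#'   `cytotoxicity`). Program genes are placed on chromosomes free of CNV
#'   events so genetic and transcriptional signals stay orthogonal.
#' @param cnv_arm_events data.frame with columns `arm`, `direction`
#'   (`gain`/`loss`), `magnitude`, `core_probability`, `margin_probability`
#'   and optionally `group` (`all`, `EGFR_amp` or `non_EGFR_amp`); each event
#'   multiplies the NB means of all genes on the arm by `1 +/- magnitude` in
#'   malignant cells that carry it (Bernoulli per cell with niche-specific
#'   probability).
#' @param pseudotime_model named character (`EGFR_amp`, `non_EGFR_amp`) with
#'   values `"coupled"` (Core ~ Beta(2,5) early, Margin ~ Beta(5,2) late) or
#'   `"uncoupled"` (both niches ~ Beta(5,2)); a single unnamed value applies
#'   to both groups.
#' @param mes_slope_amp,mes_slope_nonamp mesenchymal acquisition rates: MES
#'   program gene means are multiplied by `exp(slope * pseudotime)`.
#' @param coupling_strength slope of the sample-level myeloid suppression
#'   level on the sample endpoint fraction (in \[-1, 1\]).
#' @param coupling_noise_sd sd of the sample-level noise on the myeloid
#'   suppression level.
#' @param planted_candidates data.frame with columns `gene_id`, `coupling`,
#'   `late_fc`, `amp_fc`: candidate genes whose means in late-stage
#'   (pseudotime >= 0.75) malignant cells gain `late_fc`, additionally
#'   `amp_fc` in EGFR-amplified patients, and track the sample myeloid
#'   suppression level with strength `coupling`.
#' @param noise_dispersion NB dispersion (var = mu + dispersion * mu^2).
#' @param seed integer RNG seed.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_patients_amp = 3,
                       n_patients_nonamp = 3,
                       cells_per_sample = 500,
                       fractions = c(malignant = 0.5, myeloid = 0.25,
                                     t_cell = 0.10, reference = 0.15),
                       n_genes = 2000,
                       n_chromosomes = 10,
                       program_gene_counts = c(NPC = 50, OPC = 30, AC = 30,
                                               MES = 50,
                                               myeloid_suppression = 30,
                                               cytotoxicity = 20),
                       cnv_arm_events = data.frame(),
                       pseudotime_model = c(EGFR_amp = "uncoupled",
                                            non_EGFR_amp = "coupled"),
                       mes_slope_amp = 1.2,
                       mes_slope_nonamp = 0.6,
                       coupling_strength = 0.9,
                       coupling_noise_sd = 0.1,
                       planted_candidates = data.frame(),
                       noise_dispersion = 0.4,
                       seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop2("cell-type fractions must sum to 1", "evoniche_config_error")
  }
  if (any(fractions < 0)) {
    stop2("cell-type fractions must be non-negative", "evoniche_config_error")
  }
  if (n_patients_amp < 0 || n_patients_nonamp < 0 ||
      n_patients_amp + n_patients_nonamp < 1 || cells_per_sample < 1) {
    stop2("patient and cell counts must be positive", "evoniche_config_error")
  }
  if (length(pseudotime_model) == 1L && is.null(names(pseudotime_model))) {
    pseudotime_model <- c(EGFR_amp = unname(pseudotime_model),
                          non_EGFR_amp = unname(pseudotime_model))
  }
  if (!all(pseudotime_model %in% c("coupled", "uncoupled"))) {
    stop2("pseudotime_model values must be 'coupled' or 'uncoupled'",
          "evoniche_config_error")
  }
  cnv_arm_events <- as.data.frame(cnv_arm_events, stringsAsFactors = FALSE)
  if (nrow(cnv_arm_events) && !"group" %in% names(cnv_arm_events)) {
    cnv_arm_events$group <- "all"
  }
  planted_candidates <- as.data.frame(planted_candidates,
                                      stringsAsFactors = FALSE)
  cfg <- list(n_patients_amp = as.integer(n_patients_amp),
              n_patients_nonamp = as.integer(n_patients_nonamp),
              cells_per_sample = as.integer(cells_per_sample),
              fractions = fractions,
              n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              program_gene_counts = program_gene_counts,
              cnv_arm_events = cnv_arm_events,
              pseudotime_model = pseudotime_model,
              mes_slope_amp = mes_slope_amp,
              mes_slope_nonamp = mes_slope_nonamp,
              coupling_strength = coupling_strength,
              coupling_noise_sd = coupling_noise_sd,
              planted_candidates = planted_candidates,
              noise_dispersion = noise_dispersion,
              seed = as.integer(seed))
  n_program <- sum(program_gene_counts) + nrow(planted_candidates)
  genes_per_chrom <- n_genes %/% n_chromosomes
  event_chroms <- unique(sub("[pq]$", "", cnv_arm_events$arm))
  free_chroms <- n_chromosomes - sum(paste0(seq_len(n_chromosomes)) %in% event_chroms)
  if (n_program > free_chroms * genes_per_chrom) {
    stop2("program gene counts exceed genes available on CNV-free chromosomes",
          "evoniche_config_error")
  }
  structure(cfg, class = "SimConfig")
}

#' Default cohort-emulating simulation configuration
#'
#' Emulates the study design: 3 EGFR-amplified + 3 non-amplified patients,
#' each sampled in Core and Margin (12 sample-level units, 500 cells each),
#' chr7 gain co-occurring with EGFR amplification (both arms, probability 1 in
#' amplified patients), Core-enriched arm events shared by all patients,
#' uncoupled (niche-independent, late-skewed) pseudotime in amplified patients
#' versus a coupled Core-early/Margin-late gradient in non-amplified patients,
#' a 2x mesenchymal slope ratio, sample-level tumor-myeloid coupling 0.9, and
#' one planted strong candidate gene (`POSTN_like`).
#'
#' @param seed integer RNG seed.
#' @return a `SimConfig`.
#' @export
default_cohort_config <- function(seed = 1L) {
  events <- data.frame(
    arm = c("7p", "7q", "10p", "10q", "1p", "9q"),
    direction = c("gain", "gain", "loss", "loss", "gain", "loss"),
    magnitude = c(0.5, 0.5, 0.4, 0.4, 0.4, 0.45),
    core_probability = c(1, 1, 0.95, 0.95, 0.65, 0.60),
    margin_probability = c(1, 1, 0.90, 0.90, 0.20, 0.15),
    group = c("EGFR_amp", "EGFR_amp", "all", "all", "all", "all"),
    stringsAsFactors = FALSE)
  cands <- data.frame(gene_id = "POSTN_like", coupling = 0.9,
                      late_fc = 4, amp_fc = 3, stringsAsFactors = FALSE)
  sim_config(cnv_arm_events = events, planted_candidates = cands, seed = seed)
}

# deterministic synthetic genome: equal chromosomes, p arm = first half
make_gene_table <- function(cfg) {
  per <- cfg$n_genes %/% cfg$n_chromosomes
  extra <- cfg$n_genes - per * cfg$n_chromosomes
  sizes <- rep(per, cfg$n_chromosomes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chrom <- rep(paste0(seq_len(cfg$n_chromosomes)), sizes)
  pos <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  half <- rep(sizes, sizes) / 2
  arm <- paste0(sub("^chr", "", chrom), ifelse(pos <= half, "p", "q"))
  data.frame(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
             chromosome = chrom,
             start = pos * 1e6L,
             arm = arm,
             stringsAsFactors = FALSE)
}

# Assign program and candidate genes to chromosomes free of CNV events,
# interleaved across those chromosomes (as real transcriptional programs are
# genome-scattered) so positional CNV smoothing dilutes program effects
# instead of mistaking a contiguous program block for an arm-level event.
assign_programs <- function(cfg, genes) {
  event_chroms <- unique(sub("[pq]$", "", cfg$cnv_arm_events$arm))
  eligible <- which(!sub("^chr", "", genes$chromosome) %in% event_chroms)
  counts <- cfg$program_gene_counts
  n_cand <- nrow(cfg$planted_candidates)
  total <- sum(counts) + n_cand
  # uniform scatter over the eligible genome (drawn under the dataset seed)
  picks <- sample(eligible, total)
  programs <- list()
  offset <- 0L
  for (p in names(counts)) {
    programs[[p]] <- picks[offset + seq_len(counts[[p]])]
    offset <- offset + counts[[p]]
  }
  cand_idx <- if (n_cand) picks[offset + seq_len(n_cand)] else integer(0)
  list(programs = programs, candidate_idx = cand_idx)
}

#' Generate a synthetic ExpressionDataset with ground truth
#'
#' @param config a `SimConfig` (see [sim_config()]).
#' @return list with `dataset` (ExpressionDataset, counts only; run
#'   [log_normalize()] before analysis) and `truth` (GroundTruth: per-cell
#'   true pseudotime and CNV burden, per-sample endpoint fraction and myeloid
#'   suppression level, program gene lists, planted candidates). `truth` is
#'   test-only and never consumed by pipeline stages.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  with_seed(cfg$seed, {
    genes <- make_gene_table(cfg)
    plan <- assign_programs(cfg, genes)
    programs <- plan$programs
    cand_idx <- plan$candidate_idx
    if (length(cand_idx)) genes$gene_id[cand_idx] <- cfg$planted_candidates$gene_id

    # --- cells -----------------------------------------------------------
    patients <- c(sprintf("P%02d_amp", seq_len(cfg$n_patients_amp)),
                  sprintf("P%02d_non", seq_len(cfg$n_patients_nonamp)))
    status <- rep(c("EGFR_amp", "non_EGFR_amp"),
                  c(cfg$n_patients_amp, cfg$n_patients_nonamp))
    cps <- cfg$cells_per_sample
    n_mal <- round(cfg$fractions[["malignant"]] * cps)
    n_mye <- round(cfg$fractions[["myeloid"]] * cps)
    n_t <- round(cfg$fractions[["t_cell"]] * cps)
    n_ref <- cps - n_mal - n_mye - n_t
    if (n_ref < 0) stop2("cell-type fractions incompatible with cells_per_sample",
                         "evoniche_config_error")
    types_one <- c(rep("malignant", n_mal), rep("myeloid", n_mye),
                   rep("t_cell", n_t),
                   rep(c("reference_oligo", "reference_immune"),
                       c(ceiling(n_ref / 2), floor(n_ref / 2))))
    sample_grid <- expand.grid(niche = c("Core", "Margin"),
                               patient = patients,
                               stringsAsFactors = FALSE)[, c("patient", "niche")]
    cells <- do.call(rbind, lapply(seq_len(nrow(sample_grid)), function(s) {
      data.frame(patient = sample_grid$patient[s],
                 niche = sample_grid$niche[s],
                 cell_type = types_one,
                 stringsAsFactors = FALSE)
    }))
    cells$egfr_status <- status[match(cells$patient, patients)]
    cells$cell_id <- sprintf("C%05d", seq_len(nrow(cells)))
    n_cells <- nrow(cells)
    skey <- sample_key(cells)
    sample_ids <- unique(skey)

    # --- planted pseudotime ---------------------------------------------
    mal <- cells$cell_type == "malignant"
    amp <- cells$egfr_status == "EGFR_amp"
    pt <- rep(NA_real_, n_cells)
    model <- cfg$pseudotime_model[cells$egfr_status[mal]]
    early <- model == "coupled" & cells$niche[mal] == "Core"
    n_m <- sum(mal)
    draws <- numeric(n_m)
    draws[early] <- stats::rbeta(sum(early), 2, 5)
    draws[!early] <- stats::rbeta(sum(!early), 5, 2)
    pt[mal] <- draws

    # --- sample-level endpoint fraction and myeloid suppression ---------
    ef <- vapply(sample_ids, function(s) mean(pt[mal & skey == s] >= 0.75),
                 numeric(1))
    supp <- 0.3 + cfg$coupling_strength * ef +
      stats::rnorm(length(ef), 0, cfg$coupling_noise_sd)
    names(supp) <- sample_ids

    # --- NB mean matrix --------------------------------------------------
    mu_g <- stats::rlnorm(cfg$n_genes, meanlog = log(0.45), sdlog = 1)
    structured <- c(unlist(programs, use.names = FALSE), cand_idx)
    mu_g[structured] <- stats::runif(length(structured), 0.5, 1.5)
    M <- mu_g %o% rep(1, n_cells)

    mal_idx <- which(mal)
    t_mal <- pt[mal_idx]
    slope <- ifelse(amp[mal_idx], cfg$mes_slope_amp, cfg$mes_slope_nonamp)
    bump <- function(gene_idx, cell_idx, mult) {
      M[gene_idx, cell_idx] <<- M[gene_idx, cell_idx] *
        rep(mult, each = length(gene_idx))
    }
    bump(programs$MES, mal_idx, exp(slope * t_mal))
    bump(programs$NPC, mal_idx, exp(1.0 * (1 - t_mal)))
    bump(programs$OPC, mal_idx, exp(0.7 * (1 - t_mal)))
    bump(programs$AC, mal_idx, rep(exp(0.5), length(mal_idx)))
    mye_idx <- which(cells$cell_type == "myeloid")
    bump(programs$myeloid_suppression, mye_idx, exp(supp[skey[mye_idx]]))
    tc_idx <- which(cells$cell_type == "t_cell")
    bump(programs$cytotoxicity, tc_idx, rep(exp(0.8), length(tc_idx)))

    # --- planted candidates in late-stage malignant cells ----------------
    late_idx <- mal_idx[t_mal >= 0.75]
    if (length(cand_idx) && length(late_idx)) {
      supp_c <- supp[skey[late_idx]] - mean(supp)
      for (j in seq_along(cand_idx)) {
        pc <- cfg$planted_candidates[j, ]
        mult <- pc$late_fc * ifelse(amp[late_idx], pc$amp_fc, 1) *
          exp(pc$coupling * supp_c)
        bump(cand_idx[j], late_idx, mult)
      }
    }

    # --- arm-level CNV events in malignant cells -------------------------
    burden <- numeric(n_cells)
    ev <- cfg$cnv_arm_events
    if (nrow(ev)) {
      for (j in seq_len(nrow(ev))) {
        targets <- mal_idx[ev$group[j] == "all" |
                           cells$egfr_status[mal_idx] == ev$group[j]]
        if (!length(targets)) next
        prob <- ifelse(cells$niche[targets] == "Core",
                       ev$core_probability[j], ev$margin_probability[j])
        hit <- targets[stats::runif(length(targets)) < prob]
        if (!length(hit)) next
        arm_genes <- which(genes$arm == ev$arm[j])
        factor_ <- if (ev$direction[j] == "gain") 1 + ev$magnitude[j] else
          1 - ev$magnitude[j]
        M[arm_genes, hit] <- M[arm_genes, hit] * factor_
        burden[hit] <- burden[hit] + ev$magnitude[j]
      }
    }

    # --- draw counts -----------------------------------------------------
    counts <- matrix(stats::rnbinom(length(M), mu = M,
                                    size = 1 / cfg$noise_dispersion),
                     nrow = cfg$n_genes)
    cells$pct_mito <- 0
    cells$n_features <- as.integer(colSums(counts > 0))
    ds <- expression_dataset(counts, genes,
                             cells[, c("cell_id", "patient", "niche",
                                       "egfr_status", "cell_type",
                                       "pct_mito", "n_features")])
    truth <- structure(list(
      cells = data.frame(cell_id = cells$cell_id,
                         true_pseudotime = pt,
                         true_cnv_burden = burden,
                         stringsAsFactors = FALSE),
      samples = data.frame(sample_id = sample_ids,
                           patient = sub("\\|.*", "", sample_ids),
                           niche = sub(".*\\|", "", sample_ids),
                           egfr_status = status[match(sub("\\|.*", "", sample_ids),
                                                      patients)],
                           endpoint_fraction = unname(ef),
                           myeloid_suppression = unname(supp),
                           stringsAsFactors = FALSE),
      programs = lapply(programs, function(i) genes$gene_id[i]),
      candidates = cfg$planted_candidates,
      config = cfg), class = "GroundTruth")
    list(dataset = ds, truth = truth)
  })
}
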