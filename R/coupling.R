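# Sample-level tumor-myeloid coupling framework and PriorityScore2:
# a data-driven myeloid module summarized per sample (MyeloidAutoScore),
# per-candidate coupling (coup_rho: Spearman of late-malignant mean expression
# vs MyeloidAutoScore across samples), late-state and EGFR-specificity
# z-components, and the hard-gated weighted ranking
# PriorityScore2 = 0.40 z_coup + 0.35 z_late + 0.25 z_egfr (coup_rho > 0).

#' Per-sample summary of the tumor side of the coupling
#'
#' One row per (patient, niche) sample: the endpoint value (fraction of
#' malignant cells carrying the endpoint-program flag) plus group sizes.
#'
#' @param ds ExpressionDataset.
#' @param malignant_mask logical per-cell malignant indicator.
#' @param endpoint_flag logical endpoint membership for the malignant cells
#'   (aligned with the malignant cells in dataset order).
#' @return data.frame with `sample_id`, `patient`, `niche`, `egfr_status`,
#'   `n_malignant`, `n_myeloid`, `endpoint_value`.
#' @export
sample_summary <- function(ds, malignant_mask, endpoint_flag) {
  cells <- ds$cells
  mal <- which_index(malignant_mask, nrow(cells))
  stopifnot(length(endpoint_flag) == length(mal))
  key <- sample_key(cells)
  ids <- unique(key)
  mal_key <- key[mal]
  out <- data.frame(
    sample_id = ids,
    patient = sub("\\|.*", "", ids),
    niche = sub(".*\\|", "", ids),
    egfr_status = cells$egfr_status[match(ids, key)],
    n_malignant = vapply(ids, function(s) sum(mal_key == s), integer(1)),
    n_myeloid = vapply(ids, function(s)
      sum(cells$cell_type[key == s] == "myeloid"), integer(1)),
    stringsAsFactors = FALSE)
  out$endpoint_value <- vapply(ids, function(s) {
    f <- endpoint_flag[mal_key == s]
    if (length(f)) mean(f) else NA_real_
  }, numeric(1))
  rownames(out) <- NULL
  out
}

# genes x samples matrix of mean lognorm over one cell type
sample_mean_matrix <- function(ds, cell_selector, sample_ids) {
  L <- lognorm_matrix(ds)
  key <- sample_key(ds$cells)
  cols <- vapply(sample_ids, function(s) {
    idx <- which(key == s & cell_selector)
    if (!length(idx)) return(rep(NA_real_, nrow(L)))
    Matrix::rowMeans(L[, idx, drop = FALSE])
  }, numeric(nrow(L)))
  dimnames(cols) <- list(ds$genes$gene_id, sample_ids)
  cols
}

#' Select the data-driven myeloid suppression module
#'
#' For every gene, its sample-level mean lognorm over myeloid cells is
#' Spearman-correlated with the malignant endpoint value across samples.
#' Genes with rho >= `rho_threshold` form the module; if fewer than
#' `min_genes` pass, the top `min_genes` by |rho| are taken instead. Genes
#' constant across samples (undefined rho) are excluded with a warning.
#'
#' @param ds normalized ExpressionDataset.
#' @param samples a [sample_summary()] table (>= 4 samples with myeloid
#'   cells).
#' @param rho_threshold signed Spearman threshold (default 0.5).
#' @param min_genes minimum module size (default 5).
#' @return data.frame with `gene_id` and `rho` for the selected module.
#' @export
select_myeloid_module <- function(ds, samples, rho_threshold = 0.5,
                                  min_genes = 5) {
  is_mye <- ds$cells$cell_type == "myeloid"
  if (!any(is_mye)) stop2("no myeloid cells in dataset", "evoniche_value_error")
  usable <- samples[samples$n_myeloid > 0 & !is.na(samples$endpoint_value), ]
  if (nrow(usable) < 4) {
    stop2("need >= 4 samples with myeloid cells", "evoniche_value_error")
  }
  Msamp <- sample_mean_matrix(ds, is_mye, usable$sample_id)
  ev <- usable$endpoint_value
  rho <- apply(Msamp, 1, function(x) spearman_rho(x, ev))
  if (anyNA(rho)) {
    warning(sprintf("%d gene(s) constant across samples; excluded from module selection",
                    sum(is.na(rho))))
  }
  ok <- which(!is.na(rho))
  sel <- ok[rho[ok] >= rho_threshold]
  if (length(sel) < min_genes) {
    sel <- ok[order(abs(rho[ok]), decreasing = TRUE)][
      seq_len(min(min_genes, length(ok)))]
  }
  data.frame(gene_id = ds$genes$gene_id[sel], rho = unname(rho[sel]),
             stringsAsFactors = FALSE)
}

#' MyeloidAutoScore per sample
#'
#' Mean lognorm of the selected myeloid module genes over the myeloid cells
#' of each sample; samples without myeloid cells get NA with a warning.
#'
#' @param ds normalized ExpressionDataset.
#' @param module character vector of module gene_ids (non-empty).
#' @param samples a [sample_summary()] table.
#' @return the samples table with a `myeloid_auto_score` column added.
#' @export
myeloid_auto_score <- function(ds, module, samples) {
  if (!length(module)) stop2("empty myeloid module", "evoniche_value_error")
  idx <- match(module, ds$genes$gene_id)
  if (anyNA(idx)) {
    stop2("module gene(s) absent from dataset", "evoniche_value_error")
  }
  L <- lognorm_matrix(ds)
  key <- sample_key(ds$cells)
  is_mye <- ds$cells$cell_type == "myeloid"
  score <- vapply(samples$sample_id, function(s) {
    cols <- which(key == s & is_mye)
    if (!length(cols)) return(NA_real_)
    mean(Matrix::rowMeans(L[idx, cols, drop = FALSE]))
  }, numeric(1))
  if (anyNA(score)) {
    warning(sprintf("%d sample(s) without myeloid cells; MyeloidAutoScore NA",
                    sum(is.na(score))))
  }
  samples$myeloid_auto_score <- unname(score)
  samples
}

#' Pseudotime late-up candidate genes
#'
#' Late (pseudotime >= `late_cut`) versus early (< `early_cut`) Wilcoxon
#' differential expression within malignant cells. Candidates must reach
#' `p_adj < alpha`, `log2fc > 0`, and detection in at least `detect_frac` of
#' malignant cells; optionally intersected with a curated ligand list. The
#' late-state component is `z_late`: the candidate-set standardization of
#' `-log10(p_adj) * sign(log2fc)`.
#'
#' @param ds normalized ExpressionDataset.
#' @param malignant_mask logical per-cell malignant indicator.
#' @param pseudotime per-malignant-cell pseudotime in \[0, 1\].
#' @param ligand_list optional character vector restricting candidates.
#' @param late_cut,early_cut pseudotime strata (defaults 0.75 / 0.25).
#' @param detect_frac detectability filter (default 0.05).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data.frame with `gene_id`, `log2fc`, `p`, `p_adj`, `z_late_raw`,
#'   `z_late` for the candidate genes.
#' @export
late_up_candidates <- function(ds, malignant_mask, pseudotime,
                               ligand_list = NULL, late_cut = 0.75,
                               early_cut = 0.25, detect_frac = 0.05,
                               alpha = 0.05) {
  mal <- which_index(malignant_mask, ncol(ds$counts))
  stopifnot(length(pseudotime) == length(mal))
  late <- mal[pseudotime >= late_cut]
  early <- mal[pseudotime < early_cut]
  if (!length(late) || !length(early)) {
    stop2("empty late or early pseudotime stratum", "evoniche_empty_group")
  }
  de <- wilcoxon_de(ds, late, early)
  detected <- Matrix::rowMeans(ds$counts[, mal, drop = FALSE] > 0) >= detect_frac
  keep <- de$p_adj < alpha & de$log2fc > 0 & detected
  cand <- de[keep, , drop = FALSE]
  if (!is.null(ligand_list)) {
    cand <- cand[cand$gene_id %in% ligand_list, , drop = FALSE]
    if (!nrow(cand)) warning("no candidates remain after ligand restriction")
  }
  cand$z_late_raw <- -log10(pmax(cand$p_adj, 1e-300)) * sign(cand$log2fc)
  cand$z_late <- standardize(cand$z_late_raw)
  rownames(cand) <- NULL
  cand
}

# candidate-set z-standardization; zero variance -> all zeros
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# genes x samples mean lognorm over late-stage malignant cells
late_sample_means <- function(ds, malignant_mask, pseudotime, sample_ids,
                              late_cut = 0.75) {
  mal <- which_index(malignant_mask, ncol(ds$counts))
  late <- logical(ncol(ds$counts))
  late[mal[pseudotime >= late_cut]] <- TRUE
  sample_mean_matrix(ds, late, sample_ids)
}

#' Tumor-myeloid coupling strength of one candidate gene
#'
#' `coup_rho`: the Spearman correlation (average ranks) across samples
#' between the gene's mean lognorm in late-stage (pseudotime >= `late_cut`)
#' malignant cells and the matched sample-level MyeloidAutoScore.
#'
#' @param ds normalized ExpressionDataset.
#' @param malignant_mask,pseudotime as in [late_up_candidates()].
#' @param samples a [myeloid_auto_score()]-augmented sample table.
#' @param gene single gene_id.
#' @param late_cut late-stage pseudotime threshold (default 0.75).
#' @return Spearman rho in \[-1, 1\].
#' @export
coupling_rho <- function(ds, malignant_mask, pseudotime, samples, gene,
                         late_cut = 0.75) {
  stopifnot("myeloid_auto_score" %in% names(samples))
  Msamp <- late_sample_means(ds, malignant_mask, pseudotime,
                             samples$sample_id, late_cut)
  x <- Msamp[match(gene, rownames(Msamp)), ]
  ok <- !is.na(x) & !is.na(samples$myeloid_auto_score)
  if (sum(ok) < 4) {
    stop2("fewer than 4 samples contribute both quantities",
          "evoniche_value_error")
  }
  spearman_rho(x[ok], samples$myeloid_auto_score[ok])
}

#' EGFR-amplified specificity of candidate genes
#'
#' Raw specificity: log2 fold change (mean expm1 lognorm, eps 1e-9) of each
#' gene in late-stage malignant cells, EGFR-amplified versus non-amplified;
#' `z_egfr` is the candidate-set standardization of that statistic.
#'
#' @param ds normalized ExpressionDataset.
#' @param malignant_mask,pseudotime as in [late_up_candidates()].
#' @param genes character vector of candidate gene_ids.
#' @param late_cut late-stage pseudotime threshold (default 0.75).
#' @return data.frame with `gene_id`, `egfr_log2fc`, `z_egfr`.
#' @export
z_egfr_specificity <- function(ds, malignant_mask, pseudotime, genes,
                               late_cut = 0.75) {
  mal <- which_index(malignant_mask, ncol(ds$counts))
  late <- mal[pseudotime >= late_cut]
  amp <- late[ds$cells$egfr_status[late] == "EGFR_amp"]
  non <- late[ds$cells$egfr_status[late] == "non_EGFR_amp"]
  if (!length(amp) || !length(non)) {
    stop2("an EGFR group has no late-stage malignant cells",
          "evoniche_empty_group")
  }
  L <- lognorm_matrix(ds)
  idx <- match(genes, ds$genes$gene_id)
  eps <- 1e-9
  ma <- Matrix::rowMeans(expm1(L[idx, amp, drop = FALSE]))
  mb <- Matrix::rowMeans(expm1(L[idx, non, drop = FALSE]))
  fc <- log2((ma + eps) / (mb + eps))
  data.frame(gene_id = genes, egfr_log2fc = unname(fc),
             z_egfr = standardize(unname(fc)), stringsAsFactors = FALSE)
}

#' PriorityScore2 ranking with hard gating
#'
#' `priority_score2 = w_coup * z_coup + w_late * z_late + w_egfr * z_egfr`
#' with default weights (0.40, 0.35, 0.25). Candidates with `coup_rho <= 0`
#' are marked `gated = FALSE` and excluded from ranking; gated candidates are
#' ranked by descending score with ties broken by `coup_rho` then `gene_id`.
#'
#' @param candidates data.frame with columns `gene_id`, `coup_rho`, `z_coup`,
#'   `z_late`, `z_egfr`.
#' @param weights non-negative numeric triple summing to > 0.
#' @return the table with `priority_score2`, `gated` and `rank` columns,
#'   sorted: ranked candidates first.
#' @export
priority_score2 <- function(candidates, weights = c(0.40, 0.35, 0.25)) {
  stopifnot(all(c("gene_id", "coup_rho", "z_coup", "z_late", "z_egfr")
                %in% names(candidates)))
  if (length(weights) != 3 || any(weights < 0)) {
    stop2("weights must be three non-negative numbers", "evoniche_config_error")
  }
  if (sum(weights) == 0) {
    stop2("weights must not sum to zero", "evoniche_config_error")
  }
  out <- candidates
  out$priority_score2 <- weights[1] * out$z_coup + weights[2] * out$z_late +
    weights[3] * out$z_egfr
  out$gated <- out$coup_rho > 0
  out$rank <- NA_integer_
  g <- which(out$gated)
  if (length(g)) {
    ord <- g[order(-out$priority_score2[g], -out$coup_rho[g], out$gene_id[g])]
    out$rank[ord] <- seq_along(ord)
  }
  out <- out[order(!out$gated, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default weight-sensitivity grid
#'
#' All triples from \{0.2, 0.3, 0.4, 0.5\}^3 normalized to sum 1 (duplicates
#' removed), plus equal weights.
#'
#' @return matrix with columns `w_coup`, `w_late`, `w_egfr`.
#' @export
default_weight_grid <- function() {
  g <- as.matrix(expand.grid(w_coup = c(0.2, 0.3, 0.4, 0.5),
                             w_late = c(0.2, 0.3, 0.4, 0.5),
                             w_egfr = c(0.2, 0.3, 0.4, 0.5)))
  g <- g / rowSums(g)
  g <- unique(round(g, 10))
  rbind(g, c(1, 1, 1) / 3)
}

#' Weight-sensitivity analysis of the PriorityScore2 ranking
#'
#' Re-ranks the gated candidates under each weight setting and reports each
#' candidate's min/median/max rank and how often it lands in the top tier
#' (rank <= `top_tier`).
#'
#' @param candidates as for [priority_score2()].
#' @param weight_grid matrix of weight triples (>= 2 rows); default
#'   [default_weight_grid()].
#' @param top_tier rank cutoff for top-tier frequency (default 3).
#' @return data.frame with `gene_id`, `min_rank`, `median_rank`, `max_rank`,
#'   `top_tier_freq`.
#' @export
weight_sensitivity <- function(candidates, weight_grid = default_weight_grid(),
                               top_tier = 3) {
  weight_grid <- as.matrix(weight_grid)
  if (nrow(weight_grid) < 2) {
    stop2("need at least 2 weight settings", "evoniche_config_error")
  }
  ranks <- sapply(seq_len(nrow(weight_grid)), function(i) {
    r <- priority_score2(candidates, weight_grid[i, ])
    r$rank[match(candidates$gene_id, r$gene_id)]
  })
  ranks <- matrix(ranks, nrow = nrow(candidates))
  data.frame(
    gene_id = candidates$gene_id,
    min_rank = apply(ranks, 1, function(r) if (all(is.na(r))) NA_integer_ else
      min(r, na.rm = TRUE)),
    median_rank = apply(ranks, 1, function(r) stats::median(r, na.rm = TRUE)),
    max_rank = apply(ranks, 1, function(r) if (all(is.na(r))) NA_integer_ else
      max(r, na.rm = TRUE)),
    top_tier_freq = rowMeans(!is.na(ranks) & ranks <= top_tier),
    stringsAsFactors = FALSE)
}

#' Endpoint-program / MyeloidAutoScore linear coupling
#'
#' Ordinary least squares of `myeloid_auto_score ~ endpoint_value` across
#' samples, plus per-(EGFR status x niche) trendlines. Subgroup fits with
#' fewer than 4 samples report slope only (no p-value), mirroring the
#' small-sample caveat of stratified regressions.
#'
#' @param samples a [myeloid_auto_score()]-augmented sample table (>= 4
#'   usable samples; the predictor must vary).
#' @return list with `overall` (slope, intercept, r_squared, p, n) and
#'   `subgroups` (data.frame).
#' @export
endpoint_myeloid_regression <- function(samples) {
  use <- samples[!is.na(samples$endpoint_value) &
                 !is.na(samples$myeloid_auto_score), ]
  if (nrow(use) < 4) stop2("need >= 4 samples", "evoniche_value_error")
  if (stats::sd(use$endpoint_value) == 0) {
    stop2("endpoint_value has zero variance", "evoniche_value_error")
  }
  fit <- stats::lm(myeloid_auto_score ~ endpoint_value, data = use)
  sm <- summary(fit)
  overall <- list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  r_squared = sm$r.squared,
                  p = unname(sm$coefficients[2, 4]),
                  n = nrow(use))
  grp <- split(use, paste(use$egfr_status, use$niche, sep = "|"))
  subgroups <- do.call(rbind, lapply(names(grp), function(gname) {
    d <- grp[[gname]]
    if (nrow(d) < 2 || stats::sd(d$endpoint_value) == 0) {
      return(data.frame(group = gname, n = nrow(d), slope = NA_real_,
                        r_squared = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    f <- stats::lm(myeloid_auto_score ~ endpoint_value, data = d)
    s <- summary(f)
    data.frame(group = gname, n = nrow(d),
               slope = unname(stats::coef(f)[2]),
               r_squared = s$r.squared,
               p = if (nrow(d) >= 4) unname(s$coefficients[2, 4]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(overall = overall, subgroups = subgroups)
}

#' End-to-end candidate prioritization
#'
#' Convenience orchestrator: late-up candidate discovery, per-candidate
#' coupling against the MyeloidAutoScore, EGFR specificity, and the hard-gated
#' PriorityScore2 ranking.
#'
#' @param ds normalized ExpressionDataset.
#' @param malignant_mask,pseudotime as in [late_up_candidates()].
#' @param samples a [myeloid_auto_score()]-augmented sample table.
#' @param ligand_list optional candidate restriction.
#' @param weights PriorityScore2 weights.
#' @param late_cut late-stage pseudotime threshold (default 0.75).
#' @return ranked candidate table (see [priority_score2()]), with `coup_rho`,
#'   component z-scores and raw statistics.
#' @export
prioritize_candidates <- function(ds, malignant_mask, pseudotime, samples,
                                  ligand_list = NULL,
                                  weights = c(0.40, 0.35, 0.25),
                                  late_cut = 0.75) {
  cand <- late_up_candidates(ds, malignant_mask, pseudotime,
                             ligand_list = ligand_list, late_cut = late_cut)
  if (!nrow(cand)) return(cand)
  Msamp <- late_sample_means(ds, malignant_mask, pseudotime,
                             samples$sample_id, late_cut)
  mas <- samples$myeloid_auto_score
  rho <- vapply(cand$gene_id, function(g) {
    x <- Msamp[match(g, rownames(Msamp)), ]
    ok <- !is.na(x) & !is.na(mas)
    if (sum(ok) < 4) return(NA_real_)
    spearman_rho(x[ok], mas[ok])
  }, numeric(1))
  cand$coup_rho <- unname(rho)
  cand$coup_rho[is.na(cand$coup_rho)] <- 0
  cand$z_coup <- standardize(cand$coup_rho)
  spec <- z_egfr_specificity(ds, malignant_mask, pseudotime, cand$gene_id,
                             late_cut)
  cand$egfr_log2fc <- spec$egfr_log2fc
  cand$z_egfr <- spec$z_egfr
  priority_score2(cand, weights)
}
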