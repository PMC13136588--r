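# Reference-based CNV inference ("inferCNV-lite"): reference-centered
# relative expression, MAD clipping, positional smoothing within chromosomes,
# per-cell median centering, and global [-1, 1] normalization; the per-cell
# CIN score is the mean squared deviation from the diploid baseline,
# CIN = mean((Observed - Expected)^2), which lands in [0, 1] after the
# deviation matrix is normalized.

#' CNV inference configuration
#'
#' @param window odd number of genes in the positional moving average
#'   (default 101; shrinks at chromosome ends).
#' @param reference_cell_types cell types forming the diploid baseline
#'   (default oligodendrocyte + immune reference populations).
#' @param clip clip centered values at this many global MADs (default 3).
#' @param denoise_sd after smoothing and median centering, deviations smaller
#'   in magnitude than `denoise_sd` times the gene's reference-cell standard
#'   deviation are set to 0 (default 1.5), mirroring the denoising step of
#'   reference-based CNV inference tools; set to 0 to disable.
#' @param malignancy_threshold percentile of the reference-cell CIN
#'   distribution above which cells are called tumor clone (default 0.99).
#' @param levene_center `"mean"` (classical Levene) or `"median"`
#'   (Brown-Forsythe).
#' @return a `CnvConfig` list.
#' @export
cnv_config <- function(window = 101,
                       reference_cell_types = c("reference_oligo",
                                                "reference_immune"),
                       clip = 3,
                       denoise_sd = 1.5,
                       malignancy_threshold = 0.99,
                       levene_center = "mean") {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop2("window must be an odd integer >= 3", "evoniche_config_error")
  }
  structure(list(window = window,
                 reference_cell_types = reference_cell_types,
                 clip = clip,
                 denoise_sd = denoise_sd,
                 malignancy_threshold = malignancy_threshold,
                 levene_center = levene_center),
            class = "CnvConfig")
}

# shrinking-window running mean down the rows of a matrix
running_mean_rows <- function(B, window) {
  G <- nrow(B)
  h <- (window - 1) %/% 2
  cs <- rbind(0, apply(B, 2, cumsum))
  lo <- pmax(0L, seq_len(G) - h - 1L)
  hi <- pmin(G, seq_len(G) + h)
  (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
}

#' Infer smoothed, reference-centered CNV profiles
#'
#' Per gene, relative expression is lognorm minus the mean over reference
#' cells; values are clipped at `clip` global MADs, smoothed by a centered
#' moving average of `window` genes within each chromosome (genes sorted by
#' chromosome then start; chromosomes with fewer than 3 genes are left
#' unsmoothed with a warning), median-centered per cell, and finally divided
#' by the global maximum absolute value so deviations lie in \[-1, 1\].
#'
#' @param ds normalized ExpressionDataset with chromosome/start annotation.
#' @param cfg a [cnv_config()].
#' @return a `CnvProfile`: list with `deviation` (genes x cells, sorted by
#'   genomic position), `gene_order` (row annotation), `cin_score` (per cell,
#'   in \[0, 1\]), `arm_scores` (arms x cells mean deviation), `reference`
#'   (logical per cell), `clone_label` (filled by [call_malignant()]).
#' @export
infer_cnv_profile <- function(ds, cfg = cnv_config()) {
  L <- lognorm_matrix(ds)
  ref <- ds$cells$cell_type %in% cfg$reference_cell_types
  if (!any(ref)) stop2("no reference cells in dataset", "evoniche_value_error")
  ord <- order(chrom_order_key(ds$genes$chromosome), ds$genes$start)
  genes <- ds$genes[ord, , drop = FALSE]
  M <- as.matrix(L[ord, , drop = FALSE])
  M <- M - rowMeans(M[, ref, drop = FALSE])
  s <- stats::mad(M)
  if (s > 0) {
    lim <- cfg$clip * s
    M[M > lim] <- lim
    M[M < -lim] <- -lim
  }
  chrom_f <- factor(genes$chromosome, levels = unique(genes$chromosome))
  blocks <- split(seq_len(nrow(M)), chrom_f)
  for (b in blocks) {
    if (length(b) < 3L) {
      warning(sprintf("chromosome %s has < 3 genes; left unsmoothed",
                      genes$chromosome[b[1]]))
      next
    }
    M[b, ] <- running_mean_rows(M[b, , drop = FALSE],
                                min(cfg$window, length(b) - (length(b) + 1) %% 2))
  }
  M <- sweep(M, 2, apply(M, 2, stats::median))
  if (cfg$denoise_sd > 0) {
    refM <- M[, ref, drop = FALSE]
    ref_sd <- sqrt(pmax(rowMeans(refM^2) - rowMeans(refM)^2, 0))
    M[abs(M) < cfg$denoise_sd * ref_sd] <- 0
  }
  mx <- max(abs(M))
  if (mx > 0) M <- M / mx
  arm_f <- factor(genes$arm, levels = unique(genes$arm))
  arm_scores <- rowsum(M, arm_f) /
    as.vector(rowsum(rep(1, nrow(M)), arm_f))
  structure(list(deviation = M,
                 gene_order = genes,
                 cin_score = compute_cin_matrix(M),
                 arm_scores = arm_scores,
                 reference = ref,
                 cells = ds$cells,
                 clone_label = NULL),
            class = "CnvProfile")
}

compute_cin_matrix <- function(deviation) colMeans(deviation^2)

#' Per-cell chromosomal-instability score
#'
#' `CIN = mean over genes of deviation^2` — the mean squared deviation of the
#' (normalized) expression profile from the diploid baseline; bounded by
#' \[0, 1\] because deviations are normalized to \[-1, 1\].
#'
#' @param profile a `CnvProfile`.
#' @return named numeric vector of per-cell CIN scores.
#' @export
compute_cin <- function(profile) {
  stopifnot(inherits(profile, "CnvProfile"))
  stats::setNames(compute_cin_matrix(profile$deviation),
                  colnames(profile$deviation))
}

#' Call malignant (tumor-clone) cells from CIN scores
#'
#' The calling threshold is the `malignancy_threshold` percentile of the
#' reference cells' CIN scores. Reference-typed cells are labeled `normal`
#' regardless of score; non-reference cells above the threshold are
#' `tumor_clone`, the remainder `other`.
#'
#' @param profile a `CnvProfile` (with `cin_score`).
#' @param cfg a [cnv_config()].
#' @return the profile with `clone_label` (character per cell) and
#'   `malignancy_cutoff` filled in.
#' @export
call_malignant <- function(profile, cfg = cnv_config()) {
  stopifnot(inherits(profile, "CnvProfile"))
  thr <- unname(stats::quantile(profile$cin_score[profile$reference],
                                cfg$malignancy_threshold, type = 7))
  lab <- ifelse(profile$reference, "normal",
                ifelse(profile$cin_score > thr, "tumor_clone", "other"))
  profile$clone_label <- lab
  profile$malignancy_cutoff <- thr
  profile
}

#' Spatial genetic-polarization tests
#'
#' Per chromosome arm: Levene's test comparing the variance of per-cell arm
#' scores between Core and Margin malignant cells (BH-adjusted across arms).
#' Additionally, within each EGFR group, a Wilcoxon rank-sum test of CIN
#' scores between Core and Margin malignant cells.
#'
#' @param profile a `CnvProfile`.
#' @param malignant_mask logical per-cell malignant indicator; defaults to
#'   `clone_label == "tumor_clone"` when [call_malignant()] has run.
#' @return list with `arm_tests` (data.frame: arm, W, p, p_adj, variances)
#'   and `cin_tests` (data.frame per EGFR group).
#' @export
spatial_polarization_test <- function(profile, malignant_mask = NULL) {
  stopifnot(inherits(profile, "CnvProfile"))
  if (is.null(malignant_mask)) {
    if (is.null(profile$clone_label)) {
      stop2("run call_malignant() or supply malignant_mask",
            "evoniche_state_error")
    }
    malignant_mask <- profile$clone_label == "tumor_clone"
  }
  cells <- profile$cells
  mal <- which(malignant_mask)
  niche <- cells$niche[mal]
  arm_rows <- lapply(rownames(profile$arm_scores), function(a) {
    x <- profile$arm_scores[a, mal]
    if (sum(niche == "Core") < 3 || sum(niche == "Margin") < 3) {
      warning(sprintf("arm %s: a niche has < 3 malignant cells; skipped", a))
      return(NULL)
    }
    lt <- levene_test(x, niche)
    data.frame(arm = a, W = lt$statistic, p = lt$p.value,
               var_core = stats::var(x[niche == "Core"]),
               var_margin = stats::var(x[niche == "Margin"]),
               stringsAsFactors = FALSE)
  })
  arm_tests <- do.call(rbind, arm_rows)
  if (!is.null(arm_tests)) {
    arm_tests$p_adj <- stats::p.adjust(arm_tests$p, method = "BH")
    rownames(arm_tests) <- NULL
  }
  cin_rows <- lapply(unique(cells$egfr_status), function(g) {
    sel <- mal[cells$egfr_status[mal] == g]
    ni <- cells$niche[sel]
    if (sum(ni == "Core") < 1 || sum(ni == "Margin") < 1) return(NULL)
    w <- rank_sum_test(profile$cin_score[sel][ni == "Core"],
                       profile$cin_score[sel][ni == "Margin"])
    data.frame(egfr_status = g, p = w$p.value,
               median_core = stats::median(profile$cin_score[sel][ni == "Core"]),
               median_margin = stats::median(profile$cin_score[sel][ni == "Margin"]),
               stringsAsFactors = FALSE)
  })
  list(arm_tests = arm_tests, cin_tests = do.call(rbind, cin_rows))
}
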