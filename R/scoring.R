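# Gene-signature scoring with expression-matched control bins, tumor purity,
# and Wilcoxon differential expression.

#' Control-bin gene-module score
#'
#' For each signature gene, `n_ctrl` control genes are drawn from the same
#' average-expression bin (all genes are ranked by mean lognorm and cut into
#' `n_bins` equal-frequency bins; sampling is with replacement when the bin
#' holds fewer than `n_ctrl` genes). The per-cell score is the mean lognorm of
#' the signature genes minus the mean lognorm of the pooled control draws, so
#' random signatures score ~0 regardless of expression level.
#'
#' @param ds normalized ExpressionDataset.
#' @param signature character vector of gene_ids (genes absent from the
#'   dataset are dropped with a warning).
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
score_module <- function(ds, signature, n_bins = 24, n_ctrl = 100, seed = 0L) {
  L <- lognorm_matrix(ds)
  sig_idx <- match(signature, ds$genes$gene_id)
  if (anyNA(sig_idx)) {
    warning(sprintf("%d signature gene(s) absent from dataset; dropped",
                    sum(is.na(sig_idx))))
    sig_idx <- sig_idx[!is.na(sig_idx)]
  }
  if (!length(sig_idx)) {
    stop2("signature has no genes in the dataset", "evoniche_empty_signature")
  }
  avg <- Matrix::rowMeans(L)
  n_bins <- min(n_bins, length(avg))
  # canonical ranks (ties broken by gene_id) and gene_id-sorted pools keep
  # the seeded control draws invariant to gene and cell input order
  rnk <- integer(length(avg))
  rnk[order(avg, ds$genes$gene_id)] <- seq_along(avg)
  bin <- ceiling(rnk / (length(avg) / n_bins))
  bins <- lapply(split(seq_along(avg), bin), function(pool) {
    pool[order(ds$genes$gene_id[pool])]
  })
  ctrl_pool <- with_seed(seed, {
    unlist(lapply(sig_idx, function(g) {
      pool <- bins[[as.character(bin[g])]]
      if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
      else sample(pool, n_ctrl, replace = TRUE)
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(L[sig_idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(L[ctrl_pool, , drop = FALSE])
  stats::setNames(sig_mean - ctrl_mean, ds$cells$cell_id)
}

#' Tumor purity per sample
#'
#' Purity of each (patient, niche) sample: the fraction of its cells flagged
#' as harboring malignant copy-number events.
#'
#' @param ds ExpressionDataset.
#' @param malignant_flags logical per-cell vector (e.g. from
#'   [call_malignant()] labels, or `cell_type` labels in test mode).
#' @return data.frame with `patient`, `niche`, `n_cells`, `n_malignant`,
#'   `purity`.
#' @export
tumor_purity <- function(ds, malignant_flags) {
  stopifnot(length(malignant_flags) == ncol(ds$counts))
  key <- sample_key(ds$cells)
  ids <- unique(key)
  out <- data.frame(
    patient = sub("\\|.*", "", ids),
    niche = sub(".*\\|", "", ids),
    n_cells = as.integer(table(key)[ids]),
    n_malignant = vapply(ids, function(s) sum(malignant_flags[key == s]),
                         integer(1)),
    stringsAsFactors = FALSE)
  out$purity <- out$n_malignant / out$n_cells
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test on lognorm values between two
#' cell groups, with `log2fc = log2((mean(expm1(lognorm_A)) + eps) /
#' (mean(expm1(lognorm_B)) + eps))`, `eps = 1e-9`, and Benjamini-Hochberg
#' adjustment.
#'
#' @param ds normalized ExpressionDataset.
#' @param group_a,group_b logical or integer cell indices; both non-empty.
#' @return data.frame with `gene_id`, `log2fc`, `p`, `p_adj`.
#' @export
wilcoxon_de <- function(ds, group_a, group_b) {
  L <- lognorm_matrix(ds)
  a <- which(as.logical(seq_len(ncol(L)) %in% which_index(group_a, ncol(L))))
  b <- which(as.logical(seq_len(ncol(L)) %in% which_index(group_b, ncol(L))))
  if (!length(a) || !length(b)) {
    stop2("wilcoxon_de: both groups must be non-empty", "evoniche_empty_group")
  }
  A <- as.matrix(L[, a, drop = FALSE])
  B <- as.matrix(L[, b, drop = FALSE])
  eps <- 1e-9
  mean_a <- rowMeans(expm1(A))
  mean_b <- rowMeans(expm1(B))
  p <- vapply(seq_len(nrow(A)), function(g) {
    rank_sum_test(A[g, ], B[g, ])$p.value
  }, numeric(1))
  data.frame(gene_id = ds$genes$gene_id,
             log2fc = log2((mean_a + eps) / (mean_b + eps)),
             p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

# coerce logical/integer/character cell selectors to integer indices
which_index <- function(sel, n) {
  if (is.logical(sel)) {
    stopifnot(length(sel) == n)
    which(sel)
  } else {
    as.integer(sel)
  }
}

#' Compare signature scores across a design factor
#'
#' Cell level: two-sided Wilcoxon rank-sum. Sample level: scores are averaged
#' per (patient, niche) sample; the `niche` factor uses a paired t-test across
#' patients with both niches, the `egfr_status` factor a two-sample t-test on
#' sample means.
#'
#' @param scores numeric per-cell score vector (or one-column matrix).
#' @param design cell metadata data.frame aligned with `scores` (columns
#'   `patient`, `niche`, `egfr_status`).
#' @param factor `"niche"` or `"egfr_status"`.
#' @param level `"cell"` or `"sample"`.
#' @return list with `statistic`, `p.value`, `group_means`, `method`.
#' @export
compare_scores <- function(scores, design, factor = c("niche", "egfr_status"),
                           level = c("cell", "sample")) {
  factor <- match.arg(factor)
  level <- match.arg(level)
  scores <- as.numeric(scores)
  stopifnot(length(scores) == nrow(design))
  fac <- design[[factor]]
  lv <- if (factor == "niche") c("Core", "Margin") else
    c("EGFR_amp", "non_EGFR_amp")
  if (!all(lv %in% fac)) {
    stop2(sprintf("factor level(s) absent: %s",
                  paste(setdiff(lv, fac), collapse = ", ")),
          "evoniche_empty_group")
  }
  if (level == "cell") {
    res <- rank_sum_test(scores[fac == lv[1]], scores[fac == lv[2]])
    gm <- tapply(scores, fac, mean)
    return(list(statistic = res$statistic, p.value = res$p.value,
                group_means = gm, method = "cell-level Wilcoxon rank-sum"))
  }
  key <- sample_key(design)
  sm <- tapply(scores, key, mean)
  info <- design[!duplicated(key), c("patient", "niche", "egfr_status")]
  info$mean <- as.numeric(sm[sample_key(info)])
  if (factor == "niche") {
    wide <- merge(info[info$niche == "Core", c("patient", "mean")],
                  info[info$niche == "Margin", c("patient", "mean")],
                  by = "patient", suffixes = c("_core", "_margin"))
    if (nrow(wide) < 2) {
      stop2("need >= 2 patients with both niches for the paired t-test",
            "evoniche_empty_group")
    }
    d <- wide$mean_core - wide$mean_margin
    if (stats::sd(d) == 0) {
      tt <- list(statistic = if (all(d == 0)) 0 else Inf * sign(mean(d)),
                 p.value = if (all(d == 0)) 1 else 0)
    } else {
      ht <- stats::t.test(d)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    gm <- c(Core = mean(wide$mean_core), Margin = mean(wide$mean_margin))
    return(list(statistic = tt$statistic, p.value = tt$p.value,
                group_means = gm,
                method = "sample-level paired t-test across patients"))
  }
  g1 <- info$mean[info$egfr_status == lv[1]]
  g2 <- info$mean[info$egfr_status == lv[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    stop2("need >= 2 samples per EGFR group", "evoniche_empty_group")
  }
  if (stats::sd(c(g1, g2)) == 0) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    ht <- stats::t.test(g1, g2)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(statistic = tt$statistic, p.value = tt$p.value,
       group_means = c(stats::setNames(mean(g1), lv[1]),
                       stats::setNames(mean(g2), lv[2])),
       method = "sample-level two-sample t-test")
}
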