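# Pseudotime assignment (kNN-graph surrogate for reverse graph embedding,
# root-anchored at the NPC-like population) and evolutionary-acceleration
# kinetics: loess slope of MES acquisition, Jensen-Shannon pseudotime
# divergence, endpoint-program calls, and spatial gradient-flattening tests.

#' Graph-based pseudotime
#'
#' Surrogate trajectory: a k-nearest-neighbor graph is built on the top
#' principal components of the malignant cells' lognorm profiles and
#' pseudotime is the graph shortest-path distance from the root-cell set,
#' min-max scaled to \[0, 1\]. An externally computed pseudotime (e.g. from a
#' dedicated trajectory tool, or ground truth in simulations) can be supplied
#' via `pseudotime` and is then rescaled and returned verbatim otherwise.
#'
#' @param ds normalized ExpressionDataset.
#' @param malignant_mask logical or integer selector of malignant cells.
#' @param root_mask selector of root cells (must be a subset of
#'   `malignant_mask`, non-empty); the root population is biologically the
#'   NPC-like state.
#' @param k neighbors per cell (default 15; clamped with a warning when >=
#'   the number of cells).
#' @param n_pcs principal components (default 30).
#' @param n_var_genes at most this many top-variance genes enter the PCA
#'   (default 1000).
#' @param smooth_k,smooth_rounds before the graph is built, each cell's PC
#'   coordinates are averaged with its `smooth_k` nearest neighbors for
#'   `smooth_rounds` rounds (default: a tenth of the cells, capped at 50, for
#'   3 rounds). This denoising step substantially improves ordering recovery
#'   at single-cell noise levels; set `smooth_rounds = 0` to disable.
#' @param pseudotime optional externally computed per-cell pseudotime for the
#'   malignant cells (bypasses the graph).
#' @return named numeric vector of pseudotime in \[0, 1\] for the malignant
#'   cells; root cells get 0, cells disconnected from the root get 1 with a
#'   warning.
#' @export
compute_pseudotime <- function(ds, malignant_mask, root_mask, k = 15,
                               n_pcs = 30, n_var_genes = 1000,
                               smooth_k = NULL, smooth_rounds = 3,
                               pseudotime = NULL) {
  mal <- which_index(malignant_mask, ncol(ds$counts))
  root <- which_index(root_mask, ncol(ds$counts))
  if (!length(root)) stop2("empty root population", "evoniche_empty_group")
  if (!all(root %in% mal)) {
    stop2("root cells must be a subset of the malignant mask",
          "evoniche_value_error")
  }
  ids <- ds$cells$cell_id[mal]
  if (!is.null(pseudotime)) {
    stopifnot(length(pseudotime) == length(mal))
    rng <- range(pseudotime)
    pt <- if (diff(rng) > 0) (pseudotime - rng[1]) / diff(rng) else
      rep(0, length(pseudotime))
    return(stats::setNames(pt, ids))
  }
  n <- length(mal)
  if (k >= n) {
    warning(sprintf("k = %d >= %d cells; clamped to %d", k, n, n - 1))
    k <- n - 1
  }
  L <- lognorm_matrix(ds)
  X <- t(as.matrix(L[, mal, drop = FALSE]))            # cells x genes
  vars <- colMeans(X^2) - colMeans(X)^2
  keep <- order(vars, decreasing = TRUE)[seq_len(min(n_var_genes, ncol(X)))]
  Xc <- scale(X[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  n_pcs <- min(n_pcs, ncol(Xc), n - 1)
  eig <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  P <- Xc %*% eig$vectors[, seq_len(n_pcs), drop = FALSE]
  if (smooth_rounds > 0 && n > 2) {
    if (is.null(smooth_k)) smooth_k <- min(50L, max(5L, n %/% 10L))
    m <- min(smooth_k, n - 1)
    Dpre <- as.matrix(stats::dist(P))
    nn_s <- t(apply(Dpre, 1, function(d) order(d)[2:(m + 1)]))
    for (r in seq_len(smooth_rounds)) {
      Pn <- P
      for (i in seq_len(n)) {
        Pn[i, ] <- colMeans(P[c(i, nn_s[i, ]), , drop = FALSE])
      }
      P <- Pn
    }
  }
  D <- as.matrix(stats::dist(P))
  nn <- t(apply(D, 1, function(d) order(d)[2:(k + 1)]))
  edges <- data.frame(from = rep(seq_len(n), k),
                      to = as.vector(nn),
                      weight = D[cbind(rep(seq_len(n), k), as.vector(nn))])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")
  root_local <- match(root, mal)
  d <- igraph::distances(g, v = root_local, weights = igraph::E(g)$weight)
  d <- apply(d, 2, min)[as.character(seq_len(n))]
  if (any(!is.finite(d))) {
    warning(sprintf("%d cell(s) disconnected from the root; pseudotime set to 1",
                    sum(!is.finite(d))))
  }
  mx <- max(d[is.finite(d)])
  pt <- if (mx > 0) d / mx else rep(0, n)
  pt[!is.finite(pt)] <- 1
  stats::setNames(pt, ids)
}

#' Loess slope of program acquisition along pseudotime
#'
#' Fits `score ~ pseudotime` by local polynomial regression, evaluates the
#' fit on an even grid spanning the observed pseudotime range, and
#' differentiates by central finite differences. The mean slope summarizes
#' the acquisition rate; the maximum is also reported since either reading of
#' a kinetic "slope" is defensible.
#'
#' @param pseudotime,score aligned numeric vectors, length >= 10.
#' @param span loess span (default 0.75).
#' @param degree loess degree (default 2).
#' @param grid_n grid points (default 100).
#' @return list with `grid`, `fitted`, `slope` (per grid point), `mean_slope`,
#'   `max_slope`.
#' @export
loess_slope <- function(pseudotime, score, span = 0.75, degree = 2,
                        grid_n = 100) {
  stopifnot(length(pseudotime) == length(score))
  if (length(pseudotime) < 10) {
    stop2("need >= 10 cells for loess kinetics", "evoniche_value_error")
  }
  if (diff(range(pseudotime)) == 0) {
    stop2("degenerate pseudotime: all values equal", "evoniche_value_error")
  }
  df <- data.frame(ptime = pseudotime, score = score)
  fit <- stats::loess(score ~ ptime, data = df, span = span, degree = degree)
  grid <- seq(min(pseudotime), max(pseudotime), length.out = grid_n)
  f <- stats::predict(fit, newdata = data.frame(ptime = grid))
  slope <- rep(NA_real_, grid_n)
  h <- grid[2] - grid[1]
  slope[2:(grid_n - 1)] <- (f[3:grid_n] - f[1:(grid_n - 2)]) / (2 * h)
  slope[1] <- (f[2] - f[1]) / h
  slope[grid_n] <- (f[grid_n] - f[grid_n - 1]) / h
  list(grid = grid, fitted = f, slope = slope,
       mean_slope = mean(slope, na.rm = TRUE),
       max_slope = max(slope, na.rm = TRUE))
}

#' Jensen-Shannon divergence between two pseudotime distributions
#'
#' Histogram densities on `n_bins` shared bins over \[0, 1\] (pseudocount
#' 1e-12), base-2 JSD, so the value is symmetric and bounded by \[0, 1\];
#' fully disjoint distributions attain 1.
#'
#' @param pt_group1,pt_group2 non-empty numeric vectors with values in
#'   \[0, 1\].
#' @param n_bins shared histogram bins (default 50).
#' @return JSD in \[0, 1\].
#' @export
pseudotime_js_divergence <- function(pt_group1, pt_group2, n_bins = 50) {
  if (!length(pt_group1) || !length(pt_group2)) {
    stop2("both pseudotime samples must be non-empty", "evoniche_empty_group")
  }
  brks <- seq(0, 1, length.out = n_bins + 1)
  h <- function(x) {
    idx <- findInterval(x, brks, rightmost.closed = TRUE, all.inside = TRUE)
    p <- tabulate(idx, n_bins) / length(x) + 1e-12
    p / sum(p)
  }
  P <- h(pt_group1)
  Q <- h(pt_group2)
  M <- (P + Q) / 2
  jsd <- 0.5 * sum(P * log2(P / M)) + 0.5 * sum(Q * log2(Q / M))
  min(max(jsd, 0), 1)
}

#' Endpoint-program membership
#'
#' Flags cells in the top quartile of the global MES score distribution: the
#' threshold is the 75th percentile (linear interpolation, type 7) of the
#' pooled score vector and membership uses `>=`.
#'
#' @param mes finite numeric vector of per-cell MES scores (all malignant
#'   cells pooled across groups).
#' @return list with `flag` (logical vector) and `threshold`.
#' @export
assign_endpoint_program <- function(mes) {
  stopifnot(all(is.finite(mes)))
  thr <- unname(stats::quantile(mes, 0.75, type = 7))
  list(flag = mes >= thr, threshold = thr)
}

#' Spatial gradient-flattening report
#'
#' Quantifies whether the Core-to-Margin pseudotime gradient is intact
#' (coupled regime) or flattened (evolutionary acceleration): per EGFR group,
#' cell-level Core-vs-Margin Wilcoxon and sample-level paired t-test on
#' pseudotime, plus the amp-vs-nonamp pseudotime Wilcoxon, endpoint fractions
#' per (group, niche), and the Jensen-Shannon divergence between the two
#' groups' pseudotime distributions.
#'
#' @param pseudotime named per-cell pseudotime for malignant cells.
#' @param endpoint_flag logical endpoint-program membership, aligned.
#' @param meta cell metadata rows for the same malignant cells (columns
#'   `patient`, `niche`, `egfr_status`).
#' @return list of per-group tests and summaries; groups without both niches
#'   are reported as NULL with a warning.
#' @export
gradient_flattening_report <- function(pseudotime, endpoint_flag, meta) {
  stopifnot(length(pseudotime) == nrow(meta),
            length(endpoint_flag) == nrow(meta))
  groups <- c("EGFR_amp", "non_EGFR_amp")
  per_group <- stats::setNames(lapply(groups, function(g) {
    sel <- meta$egfr_status == g
    if (!any(sel) || length(unique(meta$niche[sel])) < 2) {
      warning(sprintf("group %s missing or single-niche; skipped", g))
      return(NULL)
    }
    pt <- pseudotime[sel]
    ni <- meta$niche[sel]
    w <- rank_sum_test(pt[ni == "Core"], pt[ni == "Margin"])
    st <- tryCatch(
      compare_scores(pt, meta[sel, , drop = FALSE], "niche", "sample"),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    list(wilcoxon_p = w$p.value,
         paired_t_p = st$p.value,
         median_gap = stats::median(pt[ni == "Core"]) -
           stats::median(pt[ni == "Margin"]),
         median_core = stats::median(pt[ni == "Core"]),
         median_margin = stats::median(pt[ni == "Margin"]))
  }), groups)
  amp <- meta$egfr_status == "EGFR_amp"
  amp_vs_nonamp <- if (any(amp) && any(!amp)) {
    list(wilcoxon_p = rank_sum_test(pseudotime[amp], pseudotime[!amp])$p.value,
         jsd = pseudotime_js_divergence(pseudotime[amp], pseudotime[!amp]))
  } else NULL
  ef <- stats::aggregate(endpoint_flag,
                         by = list(egfr_status = meta$egfr_status,
                                   niche = meta$niche), FUN = mean)
  names(ef)[3] <- "endpoint_fraction"
  list(per_group = per_group, amp_vs_nonamp = amp_vs_nonamp,
       endpoint_fractions = ef)
}
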