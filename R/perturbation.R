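# Virtual knockout in a PC-regression gene-regulatory network: zero a gene's
# outgoing (regulator) row, embed wild-type and knockout networks jointly via
# the graph Laplacian of a coupled similarity graph, and score every gene by
# the displacement of its two copies (manifold alignment distance), with
# |Z| > 1.96 adjudication and preranked enrichment of the perturbed list.

#' Build a PC-regression gene-regulatory network
#'
#' For each gene, its (z-scored) lognorm profile is regressed on the top
#' `n_pcs` principal components of the remaining genes' matrix; the
#' coefficients are back-transformed to per-gene weights. Entry (i, j) of the
#' adjacency matrix is the directed influence of regulator i on target j.
#' The matrix is sparsified to the top `top_edges_fraction` of entries by
#' |weight| and scaled so the maximum |weight| is 1. The regressions are
#' computed from the gene-gene cross-product matrix (one pass over the
#' cells), so the cost is cubic in genes, not cells. The procedure is
#' deterministic; `seed` is accepted for interface stability.
#'
#' @param ds normalized ExpressionDataset.
#' @param cell_mask selector of cells (>= 50 after masking).
#' @param n_pcs principal components per regression (default 5).
#' @param top_edges_fraction fraction of entries kept (default 0.05).
#' @param min_detect_frac genes must be expressed in at least this fraction
#'   of masked cells (default 0.05); >= 20 genes must survive.
#' @param max_genes at most this many genes enter the network, keeping the
#'   most variable detected genes (default 200).
#' @param seed unused (deterministic); kept for API stability.
#' @return a `RegulatoryNetwork`: list with `genes` and `adjacency`
#'   (genes x genes; rows are regulators).
#' @export
build_grn <- function(ds, cell_mask, n_pcs = 5, top_edges_fraction = 0.05,
                      min_detect_frac = 0.05, max_genes = 200, seed = 0L) {
  cells <- which_index(cell_mask, ncol(ds$counts))
  if (length(cells) < 50) {
    stop2("need >= 50 cells to build a GRN", "evoniche_value_error")
  }
  if (length(cells) < n_pcs + 1) {
    stop2("fewer cells than n_pcs + 1", "evoniche_value_error")
  }
  L <- lognorm_matrix(ds)
  detected <- Matrix::rowMeans(ds$counts[, cells, drop = FALSE] > 0) >=
    min_detect_frac
  if (sum(detected) < 20) {
    stop2("fewer than 20 genes detected in the masked cells",
          "evoniche_value_error")
  }
  idx <- which(detected)
  if (length(idx) > max_genes) {
    Xd <- t(as.matrix(L[idx, cells, drop = FALSE]))
    vars <- colMeans(Xd^2) - colMeans(Xd)^2
    idx <- idx[order(vars, decreasing = TRUE)[seq_len(max_genes)]]
    idx <- sort(idx)
  }
  genes <- ds$genes$gene_id[idx]
  X <- scale(t(as.matrix(L[idx, cells, drop = FALSE])))
  X[, attr(X, "scaled:scale") == 0] <- 0
  G <- ncol(X)
  A <- matrix(0, G, G, dimnames = list(genes, genes))
  k <- min(n_pcs, G - 1)
  C <- crossprod(X)                            # G x G; all regressions below
  for (j in seq_len(G)) {                      # operate on this matrix only
    e <- eigen(C[-j, -j], symmetric = TRUE)
    V <- e$vectors[, seq_len(k), drop = FALSE]
    lam <- e$values[seq_len(k)]
    lam[lam <= 1e-12] <- 1
    beta <- crossprod(V, C[-j, j]) / lam       # least squares on PC scores
    A[-j, j] <- as.vector(V %*% beta)
  }
  nz <- abs(A[A != 0])
  if (length(nz)) {
    cut <- stats::quantile(nz, 1 - top_edges_fraction, type = 7)
    A[abs(A) < cut] <- 0
    mx <- max(abs(A))
    if (mx > 0) A <- A / mx
  }
  structure(list(genes = genes, adjacency = A), class = "RegulatoryNetwork")
}

#' Construct a RegulatoryNetwork from an adjacency matrix
#'
#' @param adjacency square numeric matrix; rows are regulators (outgoing
#'   weights), columns targets.
#' @param genes gene identifiers (defaults to rownames).
#' @return a `RegulatoryNetwork`.
#' @export
regulatory_network <- function(adjacency, genes = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop2("adjacency must be square", "evoniche_dim_error")
  }
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(adjacency)))
  if (!all(is.finite(adjacency))) {
    stop2("adjacency must be finite", "evoniche_value_error")
  }
  dimnames(adjacency) <- list(genes, genes)
  structure(list(genes = genes, adjacency = adjacency),
            class = "RegulatoryNetwork")
}

#' Virtual knockout
#'
#' Zeroes the gene's outgoing weights (its regulator row) in the adjacency
#' matrix; everything else is returned unchanged, so the Frobenius difference
#' between input and output equals the norm of the zeroed row.
#'
#' @param net a `RegulatoryNetwork`.
#' @param gene gene identifier present in the network.
#' @return the knocked-out `RegulatoryNetwork`.
#' @export
virtual_knockout <- function(net, gene) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  i <- match(gene, net$genes)
  if (is.na(i)) {
    stop2(paste0("gene not in network: ", gene), "evoniche_value_error")
  }
  net$adjacency[i, ] <- 0
  net$ko_gene <- gene
  net
}

# joint Laplacian spectral embedding of two coupled similarity graphs
joint_embedding <- function(S1, S2, mu, n_dims) {
  G <- nrow(S1)
  W <- rbind(cbind(S1, diag(mu, G)), cbind(diag(mu, G), S2))
  Lp <- diag(rowSums(W)) - W
  e <- eigen(Lp, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  nontrivial <- which(vals > 1e-9)
  take <- nontrivial[seq_len(min(n_dims, length(nontrivial)))]
  E <- vecs[, take, drop = FALSE]
  # deterministic sign: first coordinate of magnitude > 1e-8 made positive
  for (cix in seq_len(ncol(E))) {
    nzi <- which(abs(E[, cix]) > 1e-8)
    if (length(nzi) && E[nzi[1], cix] < 0) E[, cix] <- -E[, cix]
  }
  E
}

#' Manifold alignment distance between wild-type and knockout networks
#'
#' The two networks' symmetrized absolute adjacencies are coupled into one
#' joint graph by unit-correspondence edges of weight `mu` between each
#' gene's wild-type and knockout copies. The joint graph Laplacian's smallest
#' nontrivial eigenvectors (`n_dims`, eigenvalues ascending, sign fixed by the
#' first non-negligible coordinate) embed both copies; the per-gene distance
#' is the Euclidean displacement between a gene's two copies. Genes in
#' connected components other than the largest are assigned distance 0 with a
#' warning.
#'
#' @param net_wt,net_ko `RegulatoryNetwork`s over the same ordered gene set.
#' @param n_dims embedding dimensions (default 2).
#' @param mu correspondence edge weight (default 0.9).
#' @return named numeric vector of non-negative per-gene distances.
#' @export
manifold_alignment_distance <- function(net_wt, net_ko, n_dims = 2, mu = 0.9) {
  stopifnot(inherits(net_wt, "RegulatoryNetwork"),
            inherits(net_ko, "RegulatoryNetwork"))
  if (!identical(net_wt$genes, net_ko$genes)) {
    stop2("networks must share the same ordered gene set", "evoniche_dim_error")
  }
  G <- length(net_wt$genes)
  S1 <- abs(net_wt$adjacency); S1 <- (S1 + t(S1)) / 2
  S2 <- abs(net_ko$adjacency); S2 <- (S2 + t(S2)) / 2
  # correspondence edges bind each gene pair, so components group gene sets:
  # a gene is detached iff it has no similarity edges in either network
  conn <- S1 + S2
  g <- igraph::graph_from_adjacency_matrix(conn > 0, mode = "undirected")
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- comp$membership == main
  dist <- stats::setNames(numeric(G), net_wt$genes)
  if (!all(in_main)) {
    warning(sprintf("%d gene(s) outside the largest component; distance 0",
                    sum(!in_main)))
  }
  idx <- which(in_main)
  if (length(idx) >= 2) {
    E <- joint_embedding(S1[idx, idx, drop = FALSE],
                         S2[idx, idx, drop = FALSE], mu, n_dims)
    gsub <- length(idx)
    d <- sqrt(rowSums((E[seq_len(gsub), , drop = FALSE] -
                       E[gsub + seq_len(gsub), , drop = FALSE])^2))
    dist[idx] <- d
  }
  dist
}

#' Z-scores and significance calls for perturbation distances
#'
#' Standardizes the manifold alignment distances over genes, excluding the
#' knocked-out gene from the mean/sd; a gene is significant iff |Z| > 1.96
#' (strict). A fold-change proxy (distance over the median distance) is
#' reported alongside.
#'
#' @param distances named per-gene distance vector (>= 10 genes).
#' @param ko_gene name of the knocked-out gene (excluded from the null
#'   moments), or NULL.
#' @return a `PerturbationResult` data.frame sorted by decreasing distance:
#'   `gene_id`, `distance`, `z_score`, `significant`, `fold_change`.
#' @export
perturbation_zscores <- function(distances, ko_gene = NULL) {
  if (length(distances) < 10) {
    stop2("need >= 10 genes for perturbation z-scores", "evoniche_value_error")
  }
  bg <- if (!is.null(ko_gene)) {
    distances[names(distances) != ko_gene]
  } else distances
  s <- stats::sd(bg)
  z <- if (!is.finite(s) || s == 0) rep(0, length(distances)) else
    (distances - mean(bg)) / s
  med <- stats::median(distances)
  out <- data.frame(gene_id = names(distances),
                    distance = unname(distances),
                    z_score = unname(z),
                    significant = unname(abs(z) > 1.96),
                    fold_change = unname(if (med > 0) distances / med else
                      rep(NA_real_, length(distances))),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$distance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("PerturbationResult", "data.frame"))
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weight |score|,
#' exponent 1) on the rank-ordered gene list, with a two-sided permutation p
#' obtained by resampling gene-set labels: `p = (1 + #{|ES_perm| >=
#' |ES_obs|}) / (n_perm + 1)`.
#'
#' @param scores named numeric vector (gene-level statistics; ranking is by
#'   decreasing score).
#' @param gene_set character vector; must intersect the ranked genes but not
#'   exhaust them.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed for permutations.
#' @return list with `es`, `p.value`, `n_hits`.
#' @export
preranked_gsea <- function(scores, gene_set, n_perm = 1000, seed = 0L) {
  stopifnot(!is.null(names(scores)))
  ord <- order(scores, decreasing = TRUE)
  genes <- names(scores)[ord]
  w <- abs(scores[ord])
  hit <- genes %in% gene_set
  n_hits <- sum(hit)
  if (n_hits == 0) {
    stop2("gene set does not intersect the ranked list",
          "evoniche_value_error")
  }
  if (n_hits == length(genes)) {
    stop2("gene set covers the whole ranked list (empty complement)",
          "evoniche_value_error")
  }
  es_stat <- function(hit) {
    sh <- sum(w[hit])
    inc <- ifelse(hit, if (sh > 0) w / sh else 1 / sum(hit),
                  -1 / (length(hit) - sum(hit)))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  es <- es_stat(hit)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ph <- logical(length(genes))
      ph[sample(length(genes), n_hits)] <- TRUE
      es_stat(ph)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(es) - 1e-12)) / (n_perm + 1)
  list(es = unname(es), p.value = p, n_hits = n_hits)
}
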