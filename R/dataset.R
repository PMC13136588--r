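# ExpressionDataset: sparse gene-by-cell counts plus gene annotation and cell
# metadata, the common currency of every pipeline stage. Counts are held as a
# Matrix::dgCMatrix; lognorm (populated by log_normalize) preserves sparsity
# because log1p(0) == 0.

GENE_COLUMNS <- c("gene_id", "chromosome", "start", "arm")
CELL_COLUMNS <- c("cell_id", "patient", "niche", "egfr_status", "cell_type")

#' Construct an ExpressionDataset
#'
#' @param counts non-negative integer matrix (genes x cells); dense or sparse.
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `arm`; one row per count-matrix row.
#' @param cells data.frame with columns `cell_id`, `patient`, `niche`
#'   (`Core`/`Margin`), `egfr_status` (`EGFR_amp`/`non_EGFR_amp`),
#'   `cell_type`, and optionally `pct_mito`, `n_features`.
#' @param lognorm optional matrix of log-normalized expression, same shape as
#'   `counts`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `counts`, `lognorm`, `genes`, `cells`.
#' @export
expression_dataset <- function(counts, genes, cells, lognorm = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  missing_g <- setdiff(GENE_COLUMNS, names(genes))
  if (length(missing_g)) {
    stop2(paste0("gene table missing columns: ", paste(missing_g, collapse = ", ")),
          "evoniche_schema_error")
  }
  missing_c <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing_c)) {
    stop2(paste0("cell table missing columns: ", paste(missing_c, collapse = ", ")),
          "evoniche_schema_error")
  }
  if (nrow(counts) != nrow(genes)) {
    stop2(sprintf("gene axis mismatch: matrix has %d rows but gene table has %d",
                  nrow(counts), nrow(genes)), "evoniche_dim_error")
  }
  if (ncol(counts) != nrow(cells)) {
    stop2(sprintf("cell axis mismatch: matrix has %d columns but cell table has %d",
                  ncol(counts), nrow(cells)), "evoniche_dim_error")
  }
  dup_g <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup_g)) {
    stop2(paste0("duplicate gene_ids: ", paste(utils::head(dup_g, 5), collapse = ", ")),
          "evoniche_duplicate_error")
  }
  dup_c <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dup_c)) {
    stop2(paste0("duplicate cell_ids: ", paste(utils::head(dup_c, 5), collapse = ", ")),
          "evoniche_duplicate_error")
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(abs(v - round(v)) > 1e-8))) {
    stop2("counts must be non-negative integers", "evoniche_value_error")
  }
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  if (!is.null(lognorm)) {
    if (!all(dim(lognorm) == dim(counts))) {
      stop2("lognorm dimensions do not match counts", "evoniche_dim_error")
    }
    dimnames(lognorm) <- dimnames(counts)
  }
  if (!"pct_mito" %in% names(cells)) {
    cells$pct_mito <- rep(NA_real_, nrow(cells))
  }
  if (!"n_features" %in% names(cells)) {
    cells$n_features <- rep(NA_integer_, nrow(cells))
  }
  structure(list(counts = counts, lognorm = lognorm,
                 genes = genes, cells = cells),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d cells (%s normalized)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$lognorm)) "not" else "log"))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Subset an ExpressionDataset
#'
#' @param x ExpressionDataset.
#' @param i gene index (integer, logical or gene_id character).
#' @param j cell index (integer, logical or cell_id character).
#' @param ... ignored.
#' @return the subsetted ExpressionDataset.
#' @export
`[.ExpressionDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$genes$gene_id)
  if (is.character(j)) j <- match(j, x$cells$cell_id)
  expression_dataset(x$counts[i, j, drop = FALSE],
                     x$genes[i, , drop = FALSE],
                     x$cells[j, , drop = FALSE],
                     lognorm = if (!is.null(x$lognorm)) x$lognorm[i, j, drop = FALSE])
}

#' Read an ExpressionDataset from disk
#'
#' Accepts a MatrixMarket coordinate file (genes x cells) or a dense TSV with
#' genes in rows, plus TSV gene and cell annotation tables with headers.
#'
#' @param matrix_path path to `.mtx` (MatrixMarket) or dense TSV counts.
#' @param genes_path TSV with columns `gene_id`, `chromosome`, `start`, `arm`.
#' @param cells_path TSV with columns `cell_id`, `patient`, `niche`,
#'   `egfr_status`, `cell_type` (optionally `pct_mito`, `n_features`).
#' @return ExpressionDataset.
#' @export
read_dataset <- function(matrix_path, genes_path, cells_path) {
  first <- readLines(matrix_path, n = 1)
  if (grepl("^%%MatrixMarket", first)) {
    counts <- Matrix::readMM(matrix_path)
  } else {
    counts <- as.matrix(utils::read.delim(matrix_path, header = FALSE))
  }
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE,
                             colClasses = c(gene_id = "character",
                                            chromosome = "character",
                                            arm = "character"))
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE,
                             colClasses = c(cell_id = "character",
                                            patient = "character"))
  expression_dataset(counts, genes, cells)
}

#' Write an ExpressionDataset to disk
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate), `genes.tsv` and `cells.tsv`
#' into `out_dir`; `read_dataset` on the result reproduces counts and both
#' annotation tables exactly.
#'
#' @param ds ExpressionDataset.
#' @param out_dir output directory (created if absent).
#' @return named character vector of written paths (the manifest), invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop2(paste0("cannot create output directory: ", out_dir), "evoniche_io_error")
  }
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "genes.tsv"),
             cells = file.path(out_dir, "cells.tsv"))
  Matrix::writeMM(ds$counts, paths[["matrix"]])
  utils::write.table(ds$genes, paths[["genes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$cells, paths[["cells"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Quality-control filter
#'
#' Removes apoptotic debris: cells with mitochondrial content strictly above
#' `max_pct_mito` percent or strictly fewer than `min_features` detected
#' genes. Boundary cells (exactly 20 / exactly 200 under the defaults) are
#' retained. `pct_mito` and `n_features` are recomputed from counts when
#' absent; mitochondrial genes are identified by `mito_prefix` on gene_id.
#'
#' @param ds ExpressionDataset.
#' @param max_pct_mito maximum tolerated mitochondrial percentage (default 20).
#' @param min_features minimum detected features (default 200).
#' @param mito_prefix gene_id prefix marking mitochondrial genes (default
#'   `"MT-"`).
#' @return list with `dataset` (filtered ExpressionDataset) and `report`
#'   (cells removed per criterion).
#' @export
qc_filter <- function(ds, max_pct_mito = 20, min_features = 200,
                      mito_prefix = "MT-") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  cells <- ds$cells
  totals <- Matrix::colSums(ds$counts)
  if (anyNA(cells$pct_mito)) {
    mito <- startsWith(ds$genes$gene_id, mito_prefix)
    mito_counts <- if (any(mito)) {
      Matrix::colSums(ds$counts[mito, , drop = FALSE])
    } else {
      numeric(ncol(ds$counts))
    }
    pct <- ifelse(totals > 0, 100 * mito_counts / totals, 0)
    cells$pct_mito <- ifelse(is.na(cells$pct_mito), pct, cells$pct_mito)
  }
  if (anyNA(cells$n_features)) {
    nf <- Matrix::colSums(ds$counts > 0)
    cells$n_features <- ifelse(is.na(cells$n_features), nf, cells$n_features)
  }
  fail_mito <- cells$pct_mito > max_pct_mito
  fail_feat <- cells$n_features < min_features
  keep <- !(fail_mito | fail_feat)
  report <- list(n_input = nrow(cells),
                 n_removed_pct_mito = sum(fail_mito),
                 n_removed_min_features = sum(fail_feat),
                 n_removed = sum(!keep),
                 n_retained = sum(keep),
                 max_pct_mito = max_pct_mito,
                 min_features = min_features)
  if (!any(keep)) {
    warning("qc_filter removed every cell; returning an empty dataset")
  }
  ds$cells <- cells
  out <- ds[, which(keep)]
  list(dataset = out, report = report)
}

#' Library-size log normalization
#'
#' `lognorm[g, c] = log1p(scale * counts[g, c] / total_counts[c])`
#' (log1p-CPM at the default `scale = 1e4`). Cells with zero total counts get
#' an all-zero column and a warning.
#'
#' @param ds ExpressionDataset.
#' @param scale library-size scale factor (default `1e4`).
#' @return the dataset with `lognorm` populated.
#' @export
log_normalize <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "ExpressionDataset"), scale > 0)
  totals <- Matrix::colSums(ds$counts)
  if (any(totals == 0)) {
    warning(sprintf("%d cell(s) have zero total counts; lognorm set to zero",
                    sum(totals == 0)))
  }
  inv <- ifelse(totals > 0, scale / totals, 0)
  ds$lognorm <- log1p(ds$counts %*% Matrix::Diagonal(x = inv))
  dimnames(ds$lognorm) <- dimnames(ds$counts)
  ds
}

# dense lognorm accessor with guard
lognorm_matrix <- function(ds) {
  if (is.null(ds$lognorm)) {
    stop2("dataset is not normalized; call log_normalize() first",
          "evoniche_state_error")
  }
  ds$lognorm
}

# (patient, niche) sample key
sample_key <- function(cells) paste(cells$patient, cells$niche, sep = "|")
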