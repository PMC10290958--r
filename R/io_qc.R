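# Reading UMI count matrices, QC filtering, normalization, residualization.

#' Construct a cells x genes count matrix
#'
#' @param counts cells x genes matrix of non-negative integers (dense or
#'   sparse), with unique cell rownames and gene colnames.
#' @param mito logical per gene; if `NULL`, flagged by `mito_prefix`.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return object of class `count_matrix`: list with `counts` (dgCMatrix),
#'   `gene_ids`, `cell_ids`, `mito`.
#' @export
count_matrix <- function(counts, mito = NULL, mito_prefix = "MT-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  gene_ids <- colnames(counts)
  cell_ids <- rownames(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("counts must carry cell rownames and gene colnames")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  v <- counts@x
  if (any(v < 0)) stop("negative counts are not allowed")
  if (any(v != round(v))) stop("counts must be integers")
  if (is.null(mito)) mito <- startsWith(gene_ids, mito_prefix)
  stopifnot(length(mito) == length(gene_ids))
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 mito = mito),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%d mitochondrial)\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito)))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Accepts either a 10x-style directory containing `matrix.mtx` (genes x
#' cells Matrix Market triplet), `genes.tsv` and `barcodes.tsv`, or a dense
#' CSV/TSV file with cells as rows (first column = cell id, header = gene
#' ids).
#'
#' @param path directory (MTX) or file (CSV/TSV).
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, mito_prefix = "MT-") {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(file.path(path, "barcodes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("matrix dimensions do not match genes.tsv/barcodes.tsv")
    }
    m <- Matrix::t(m)  # stored genes x cells, used cells x genes
    dimnames(m) <- list(cells, genes)
    count_matrix(m, mito_prefix = mito_prefix)
  } else if (file.exists(path)) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    count_matrix(as.matrix(df), mito_prefix = mito_prefix)
  } else {
    stop("no such file or directory: ", path)
  }
}

#' Write a count matrix as a 10x-style MTX triplet directory
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv`, `barcodes.tsv`.
#'
#' @param x a [count_matrix()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' QC thresholds
#'
#' Defaults follow the standard droplet QC applied to proliferating
#' adipocyte progenitors: cells with fewer than 200 or more than 9,000
#' detected genes, more than 120,000 UMIs, or (when the mitochondrial filter
#' is active) a mitochondrial fraction higher than 8% are removed; genes
#' expressed in fewer than three cells are then dropped. All rules use
#' strict inequalities. The mitochondrial filter is switchable because the
#' mitochondrial fraction legitimately rises during adipogenesis and should
#' not be used to filter differentiating cells.
#'
#' @param min_genes,max_genes detected-gene bounds per cell.
#' @param max_umis maximum UMI total per cell.
#' @param max_mito_fraction maximum mitochondrial fraction per cell.
#' @param min_cells_per_gene minimum number of cells expressing a gene.
#' @param apply_mito_filter logical switch for the mitochondrial rule.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 9000L,
                          max_umis = 120000L, max_mito_fraction = 0.08,
                          min_cells_per_gene = 3L, apply_mito_filter = TRUE) {
  stopifnot(min_genes < max_genes, min_genes > 0, max_umis > 0,
            max_mito_fraction > 0, min_cells_per_gene > 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_umis = max_umis, max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 apply_mito_filter = apply_mito_filter),
            class = "qc_thresholds")
}

#' Per-cell QC covariates
#'
#' @param x a [count_matrix()].
#' @return data.frame with cell_id, umi_total, n_genes, mito_fraction
#'   (computed on raw counts).
#' @export
cell_qc_stats <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  umi <- Matrix::rowSums(x$counts)
  ngene <- Matrix::rowSums(x$counts > 0)
  mt <- if (any(x$mito)) {
    Matrix::rowSums(x$counts[, x$mito, drop = FALSE]) / pmax(umi, 1)
  } else rep(0, length(umi))
  data.frame(cell_id = x$cell_ids, umi_total = as.numeric(umi),
             n_genes = as.integer(ngene), mito_fraction = as.numeric(mt),
             stringsAsFactors = FALSE)
}

#' Filter cells and genes by QC rules
#'
#' Cells are filtered first (detected genes strictly below `min_genes` or
#' strictly above `max_genes`; UMIs strictly above `max_umis`; mitochondrial
#' fraction strictly above `max_mito_fraction` when the filter is active),
#' then genes expressed in fewer than `min_cells_per_gene` of the surviving
#' cells are removed. Filtering is idempotent.
#'
#' @param x a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `counts` (filtered [count_matrix()]) and `report`
#'   (per-rule removal counts; a cell violating several rules is counted
#'   under each, `cells_removed` is the size of the union).
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  st <- cell_qc_stats(x)
  low  <- st$n_genes < thresholds$min_genes
  high <- st$n_genes > thresholds$max_genes
  umi  <- st$umi_total > thresholds$max_umis
  mito <- if (thresholds$apply_mito_filter)
    st$mito_fraction > thresholds$max_mito_fraction else rep(FALSE, nrow(st))
  drop_cell <- low | high | umi | mito
  if (all(drop_cell)) stop("QC filtering removed all cells")
  kept <- x$counts[!drop_cell, , drop = FALSE]
  expressed_in <- Matrix::colSums(kept > 0)
  drop_gene <- expressed_in < thresholds$min_cells_per_gene
  out <- count_matrix(kept[, !drop_gene, drop = FALSE],
                      mito = x$mito[!drop_gene])
  report <- list(
    cells_in = nrow(x$counts),
    cells_removed_low_genes = sum(low),
    cells_removed_high_genes = sum(high),
    cells_removed_high_umi = sum(umi),
    cells_removed_high_mito = sum(mito),
    cells_removed = sum(drop_cell),
    cells_kept = sum(!drop_cell),
    genes_in = ncol(x$counts),
    genes_removed_low_cells = sum(drop_gene),
    genes_kept = sum(!drop_gene),
    thresholds = unclass(thresholds))
  list(counts = out, report = report)
}

#' Library-size log normalization
#'
#' Scales each cell to `target_sum` total counts and applies `log(1 + x)`
#' (natural log). Per-cell scale factors are retained so non-log profiles
#' can be recovered exactly by `expm1()` (see [build_stratum_profiles()]).
#'
#' @param x a filtered [count_matrix()].
#' @param target_sum common transcript count per cell.
#' @return object of class `normalized_matrix`: list with `values` (dense
#'   cells x genes matrix), `transform`, `size_factors`, `target_sum`,
#'   `mito`.
#' @export
normalize_log <- function(x, target_sum = 10000) {
  stopifnot(inherits(x, "count_matrix"), target_sum > 0)
  umi <- Matrix::rowSums(x$counts)
  if (any(umi == 0)) {
    stop("zero-count cell encountered; run qc_filter() first")
  }
  sf <- target_sum / umi
  vals <- log1p(as.matrix(x$counts) * sf)
  structure(list(values = vals, transform = "log-normalized",
                 size_factors = as.numeric(sf), target_sum = target_sum,
                 mito = x$mito),
            class = "normalized_matrix")
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d cells x %d genes\n",
              x$transform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Residualize expression against technical covariates
#'
#' Per gene, replaces log-normalized expression by ordinary-least-squares
#' residuals against an intercept plus the given covariates (typically UMI
#' total and mitochondrial fraction). Constant covariate columns are dropped
#' with a warning.
#'
#' @param norm a [normalize_log()] result.
#' @param covariates data.frame or matrix of per-cell covariates, rows
#'   aligned to cells.
#' @return a `normalized_matrix` with `transform = "residualized"`.
#' @export
residualize <- function(norm, covariates) {
  stopifnot(inherits(norm, "normalized_matrix"))
  X <- as.matrix(covariates)
  if (nrow(X) != nrow(norm$values)) {
    stop("covariates must have one row per cell")
  }
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  D <- cbind(Intercept = 1, X)
  qrD <- qr(D)
  res <- norm$values - qr.fitted(qrD, norm$values)
  out <- norm
  out$values <- res
  out$transform <- "residualized"
  out
}

#' Z-score scaling with clipping (for embeddings)
#'
#' Centers and scales each gene to unit variance and clips at +/- `clip`.
#' Used only for embedding/clustering, never for curve fitting, because
#' clipping distorts the expression values that the smoothed curves and the
#' divergence calls are computed on.
#'
#' @param norm a `normalized_matrix`.
#' @param clip clip bound in sd units.
#' @return dense cells x genes matrix.
#' @export
scale_clip <- function(norm, clip = 10) {
  v <- scale(norm$values)
  v[is.na(v)] <- 0
  pmin(pmax(v, -clip), clip)
}
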