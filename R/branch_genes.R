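# Branch-dependent gene testing: spline likelihood-ratio test between a
# full model (spline(t) * branch) and a reduced model (spline(t)), BH
# correction, effect-size filtering and kinetic clustering.

#' Average log fold change between branches
#'
#' Mean log-normalized expression over U cells minus the mean over L cells,
#' reported on the log2 scale (the conventional genomics "log fold change"
#' unit; internal normalization uses natural log1p, so the difference is
#' divided by log(2)).
#'
#' @param norm a `normalized_matrix`.
#' @param meta data.frame with `cell_id` and `branch`; only U/L cells enter.
#' @return named numeric vector, one value per gene (U minus L).
#' @export
avg_logfc <- function(norm, meta) {
  stopifnot(inherits(norm, "normalized_matrix"))
  br <- meta$branch[match(rownames(norm$values), meta$cell_id)]
  iu <- which(br == "U"); il <- which(br == "L")
  if (!length(iu) || !length(il)) stop("both U and L branches must be populated")
  (colMeans(norm$values[iu, , drop = FALSE]) -
     colMeans(norm$values[il, , drop = FALSE])) / log(2)
}

#' Branch-dependent gene likelihood-ratio test
#'
#' Fits, per gene, a full model `expression ~ ns(t, df) * branch` and a
#' reduced model `expression ~ ns(t, df)` on U/L cells only (progenitor
#' cells are excluded from the two-branch contrast) and computes the
#' likelihood-ratio statistic `2 * (l_full - l_reduced)`, a chi-square
#' p-value with df equal to the difference in parameter count, and BH
#' q-values across genes.
#'
#' The default family is Gaussian on log-normalized expression (fast, fitted
#' for all genes simultaneously through a shared QR decomposition). The
#' negative-binomial family refits each gene by `MASS::glm.nb` on raw counts
#' with a log library-size offset; it is substantially slower and intended
#' for small gene panels.
#'
#' @param norm a `normalized_matrix` of log-normalized expression.
#' @param meta data.frame with `cell_id`, `branch`, `pseudotime_stretched`.
#' @param spline_df degrees of freedom of the natural cubic spline basis.
#' @param family `"gaussian"` (default) or `"negbin"`.
#' @param counts a [count_matrix()], required for `family = "negbin"`.
#' @param q_max,lfc_min significance filters applied to the `significant`
#'   flag (strict inequalities: q < q_max and |logFC| > lfc_min).
#' @return data.frame with gene_id, lr_statistic, p, q, avg_logfc,
#'   significant.
#' @export
fit_branch_test <- function(norm, meta, spline_df = 3L,
                            family = c("gaussian", "negbin"), counts = NULL,
                            q_max = 0.05, lfc_min = 0.3) {
  family <- match.arg(family)
  stopifnot(inherits(norm, "normalized_matrix"))
  m <- meta[match(rownames(norm$values), meta$cell_id), ]
  ul <- which(m$branch %in% c("U", "L"))
  if (length(ul) < 2 * (spline_df + 2)) stop("too few U/L cells for the fit")
  t <- m$pseudotime_stretched[ul]
  br <- factor(m$branch[ul], levels = c("L", "U"))
  B <- splines::ns(t, df = spline_df)
  Xf <- stats::model.matrix(~ B * br)
  Xr <- stats::model.matrix(~ B)
  df_diff <- ncol(Xf) - ncol(Xr)

  Y <- norm$values[ul, , drop = FALSE]
  n <- nrow(Y)
  gene_ids <- colnames(Y)

  if (family == "gaussian") {
    rss <- function(X) {
      qrX <- qr(X)
      colSums((Y - qr.fitted(qrX, Y))^2)
    }
    rss_f <- rss(Xf); rss_r <- rss(Xr)
    zerovar <- matrixStats_colVars(Y) == 0
    lr <- n * (log(pmax(rss_r, .Machine$double.eps)) -
                 log(pmax(rss_f, .Machine$double.eps)))
    lr <- pmax(lr, 0)
    p <- stats::pchisq(lr, df = df_diff, lower.tail = FALSE)
    p[zerovar] <- 1
    lr[zerovar] <- 0
  } else {
    if (is.null(counts)) stop("family = 'negbin' requires the counts matrix")
    cts <- as.matrix(counts$counts)[rownames(norm$values)[ul], gene_ids,
                                    drop = FALSE]
    off <- log(Matrix::rowSums(counts$counts)[rownames(norm$values)[ul]])
    lr <- p <- numeric(length(gene_ids))
    for (j in seq_along(gene_ids)) {
      y <- cts[, j]
      if (stats::var(y) == 0) { lr[j] <- 0; p[j] <- 1; next }
      fit_f <- try(suppressWarnings(
        MASS::glm.nb(y ~ Xf - 1 + offset(off))), silent = TRUE)
      fit_r <- try(suppressWarnings(
        MASS::glm.nb(y ~ Xr - 1 + offset(off))), silent = TRUE)
      if (inherits(fit_f, "try-error") || inherits(fit_r, "try-error")) {
        lr[j] <- 0; p[j] <- 1; next
      }
      lr[j] <- max(0, 2 * (stats::logLik(fit_f) - stats::logLik(fit_r)))
      p[j] <- stats::pchisq(lr[j], df = df_diff, lower.tail = FALSE)
    }
  }
  q <- bh_adjust(p)
  lfc <- avg_logfc(norm, meta)
  res <- data.frame(
    gene_id = gene_ids, lr_statistic = as.numeric(lr), p = as.numeric(p),
    q = q, avg_logfc = as.numeric(lfc[gene_ids]),
    stringsAsFactors = FALSE)
  res$significant <- res$q < q_max & abs(res$avg_logfc) > lfc_min
  rownames(res) <- NULL
  res
}

#' @keywords internal
matrixStats_colVars <- function(Y) {
  n <- nrow(Y)
  (colSums(Y^2) - n * colMeans(Y)^2) / (n - 1)
}

#' Filter branch-test results on significance and effect size
#'
#' Keeps genes with q strictly below `q_max` and absolute average log fold
#' change strictly above `lfc_min`.
#'
#' @param results a [fit_branch_test()] result.
#' @param q_max,lfc_min thresholds (strict inequalities).
#' @return character vector of gene ids.
#' @export
filter_branch_genes <- function(results, q_max = 0.05, lfc_min = 0.3) {
  stopifnot(all(c("gene_id", "q", "avg_logfc") %in% names(results)))
  results$gene_id[results$q < q_max & abs(results$avg_logfc) > lfc_min]
}

#' Kinetic clustering of branch-dependent genes
#'
#' Concatenates each gene's smoothed U and L curves, z-scores the
#' concatenated profile per gene, and clusters genes by hierarchical
#' clustering (Ward linkage on correlation distance `1 - r`), cut at `k`
#' clusters.
#'
#' @param curves a [smooth_branch_curves()] result.
#' @param genes character vector of (significant) gene ids to cluster.
#' @param k number of kinetic clusters.
#' @return named integer vector of cluster ids (1..k) per gene.
#' @export
kinetic_clusters <- function(curves, genes, k = 6L) {
  stopifnot(inherits(curves, "branch_curves"), k >= 1L)
  genes <- intersect(genes, colnames(curves$curves$U))
  if (length(genes) < k) {
    stop(sprintf("need at least k = %d genes, got %d", k, length(genes)))
  }
  M <- cbind(t(curves$curves$U[, genes, drop = FALSE]),
             t(curves$curves$L[, genes, drop = FALSE]))
  M <- t(apply(M, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  if (k == 1L) {
    return(stats::setNames(rep(1L, length(genes)), genes))
  }
  cm <- suppressWarnings(stats::cor(t(M)))
  cm[is.na(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "ward.D2")
  stats::setNames(stats::cutree(hc, k = k), genes)
}
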