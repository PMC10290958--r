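# Joint PCA embedding of a reference and a query dataset, and kNN label
# transfer with vote-fraction confidence scores. A deliberately simple
# stand-in for panorama-stitching integration methods: the acceptance
# surface is label recovery, not batch-effect correction.

#' Joint PCA embedding of reference and query
#'
#' Intersects genes, log-normalizes both datasets to a common transcript
#' total, centers and scales each gene on the concatenated set, and fits a
#' single PCA; both datasets are represented in the same principal-component
#' space.
#'
#' @param ref,query [count_matrix()] objects, or plain cells x genes
#'   matrices of counts with dimnames.
#' @param n_pcs number of principal components.
#' @param min_shared minimum number of shared genes required.
#' @param target_sum library-size normalization target.
#' @return list with `ref` and `query` score matrices (cells x n_pcs),
#'   `rotation`, and `genes` (the shared gene set, sorted).
#' @export
joint_embed <- function(ref, query, n_pcs = 50L, min_shared = 200L,
                        target_sum = 10000) {
  as_cm <- function(x) if (inherits(x, "count_matrix")) x else count_matrix(x)
  ref <- as_cm(ref); query <- as_cm(query)
  shared <- sort(intersect(ref$gene_ids, query$gene_ids))
  if (length(shared) < min_shared) {
    stop(sprintf("only %d shared genes (< %d)", length(shared), min_shared))
  }
  lognorm <- function(cm) {
    umi <- Matrix::rowSums(cm$counts)
    if (any(umi == 0)) stop("zero-count cell in input")
    log1p(as.matrix(cm$counts[, shared, drop = FALSE]) * (target_sum / umi))
  }
  A <- lognorm(ref); B <- lognorm(query)
  X <- rbind(A, B)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sd, "/")
  n_pcs <- min(n_pcs, ncol(X) - 1L, nrow(X) - 1L)
  pc <- stats::prcomp(X, rank. = n_pcs, center = FALSE, scale. = FALSE)
  list(ref = pc$x[seq_len(nrow(A)), , drop = FALSE],
       query = pc$x[nrow(A) + seq_len(nrow(B)), , drop = FALSE],
       rotation = pc$rotation, genes = shared)
}

#' kNN label transfer with vote-fraction confidences
#'
#' Euclidean k-nearest-neighbour classification of query cells against
#' reference cells in a shared embedding. The predicted label is the
#' plurality vote (ties broken by alphabetical label order, deterministic),
#' and the confidence is the fraction of the k neighbours voting for it.
#'
#' @param embedding a [joint_embed()] result, or a list with `ref` and
#'   `query` score matrices.
#' @param ref_labels character vector of reference labels, one per
#'   reference cell.
#' @param k number of neighbours (0 < k <= reference size).
#' @return data.frame with cell_id, label, confidence; the full vote
#'   fraction matrix (queries x labels, rows summing to 1) is attached as
#'   attribute `"votes"`.
#' @export
knn_transfer <- function(embedding, ref_labels, k = 15L) {
  R <- embedding$ref; Q <- embedding$query
  if (k <= 0) stop("k must be positive")
  if (k > nrow(R)) stop("k exceeds the reference size")
  stopifnot(length(ref_labels) == nrow(R))
  labs <- sort(unique(ref_labels))
  # squared Euclidean distances query x reference
  d2 <- outer(rowSums(Q^2), rowSums(R^2), "+") - 2 * Q %*% t(R)
  votes <- matrix(0, nrow(Q), length(labs),
                  dimnames = list(rownames(Q), labs))
  pred <- character(nrow(Q)); conf <- numeric(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(factor(ref_labels[nn], levels = labs))
    votes[i, ] <- as.numeric(tab) / k
    pred[i] <- labs[which.max(tab)]  # which.max takes the first = alphabetical
    conf[i] <- max(tab) / k
  }
  out <- data.frame(
    cell_id = rownames(Q) %||% sprintf("query_%d", seq_len(nrow(Q))),
    label = pred, confidence = conf, stringsAsFactors = FALSE)
  attr(out, "votes") <- votes
  out
}
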