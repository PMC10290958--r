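# Stretched pseudotime, branch x decile stratification, and a simplified
# bifurcation-inference stand-in (PCA -> k-means -> MST).

#' Stretch raw pseudotime to the 0-100 scale
#'
#' Each root-to-leaf path (P -> U and P -> L) is mapped to \[0, 100\] so that
#' the least progressed cell on a path sits at 0 and the most progressed at
#' 100. Shared progenitor cells receive identical values on both paths: the
#' P segment is mapped affinely onto \[0, B\] where B is the branch point's
#' position under global min-max scaling, and each leaf segment onto
#' \[B, 100\]. The construction is invariant to affine transforms of the raw
#' pseudotime and preserves order within every path.
#'
#' @param meta data.frame with columns `cell_id`, `branch` (in P/U/L) and
#'   `pseudotime_raw` (finite, >= 0).
#' @return `meta` with a `pseudotime_stretched` column in \[0, 100\].
#' @export
stretch_pseudotime <- function(meta) {
  stopifnot(all(c("cell_id", "branch", "pseudotime_raw") %in% names(meta)))
  t <- meta$pseudotime_raw
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("raw pseudotime must be finite and >= 0")
  }
  br <- meta$branch
  stopifnot(all(br %in% c("P", "U", "L")))
  out <- rep(NA_real_, nrow(meta))

  leaves <- intersect(c("U", "L"), unique(br))
  has_p <- any(br == "P")
  if (length(leaves) == 0L) {
    # single path consisting of P cells only
    rng <- range(t)
    if (diff(rng) == 0) stop("path with all-equal raw pseudotime")
    out <- 100 * (t - rng[1]) / diff(rng)
  } else if (!has_p) {
    for (b in leaves) {
      i <- br == b
      rng <- range(t[i])
      if (diff(rng) == 0) stop("path with all-equal raw pseudotime")
      out[i] <- 100 * (t[i] - rng[1]) / diff(rng)
    }
  } else {
    m <- min(t[br == "P"])
    b_raw <- max(t[br == "P"])  # branch point: end of the shared segment
    maxima <- vapply(leaves, function(b) max(t[br == b], numeric(1)),
                     numeric(1))
    M <- max(b_raw, maxima)
    if (M == m) stop("path with all-equal raw pseudotime")
    B <- 100 * (b_raw - m) / (M - m)
    i <- br == "P"
    if (b_raw == m) stop("path with all-equal raw pseudotime")
    out[i] <- B * (t[i] - m) / (b_raw - m)
    for (b in leaves) {
      j <- br == b
      Mb <- max(t[j])
      if (Mb <= b_raw) {
        # leaf degenerate w.r.t. the branch point: clamp onto [B, 100]
        out[j] <- ifelse(t[j] >= b_raw, 100, B * (t[j] - m) / (b_raw - m))
      } else {
        out[j] <- B + (100 - B) * pmax(t[j] - b_raw, 0) / (Mb - b_raw)
      }
    }
  }
  meta$pseudotime_stretched <- out
  meta
}

#' Stratify cells into branch x pseudotime-decile groups
#'
#' Within each branch, cells are ranked by stretched pseudotime (ties broken
#' by cell id for determinism) and split into `n_bins` near-equal-count
#' quantile bins. With three populated branches and the default 10 bins this
#' yields the canonical 30 strata.
#'
#' @param meta data.frame with `cell_id`, `branch`, `pseudotime_stretched`.
#' @param n_bins number of quantile bins per branch (default 10 deciles).
#' @return data.frame with `cell_id`, `branch`, `decile`, `stratum`
#'   (branch.decile string).
#' @export
stratify_deciles <- function(meta, n_bins = 10L) {
  stopifnot(all(c("cell_id", "branch", "pseudotime_stretched") %in% names(meta)),
            n_bins >= 1L)
  pieces <- lapply(split(meta, meta$branch), function(d) {
    if (nrow(d) < n_bins) {
      stop(sprintf(
        "branch '%s' has %d cells, fewer than %d bins; lower n_bins",
        d$branch[1], nrow(d), n_bins))
    }
    o <- order(d$pseudotime_stretched, d$cell_id)
    dec <- integer(nrow(d))
    dec[o] <- ceiling(seq_len(nrow(d)) * n_bins / nrow(d))
    data.frame(cell_id = d$cell_id, branch = d$branch, decile = dec,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[match(meta$cell_id, out$cell_id), ]
  rownames(out) <- NULL
  out$stratum <- paste(out$branch, out$decile, sep = ".")
  out
}

#' Infer a bifurcating trajectory (simplified stand-in)
#'
#' A deliberately simple substitute for tree-embedding trajectory methods:
#' PCA on the top-variance genes, k-means centroids, a minimum spanning tree
#' over the centroids, root selection, and branch assignment at the first
#' degree >= 3 node on the tree. Cell pseudotime is the tree geodesic from
#' the root to the cell's centroid plus the cell's projection onto the
#' adjacent tree edge. Branch labels U/L are arbitrary unless `marker_genes`
#' is supplied, in which case the branch with the higher mean marker
#' expression is called U (the adipogenic branch, by convention).
#'
#' @param norm a `normalized_matrix` (optionally residualized).
#' @param n_pcs number of principal components.
#' @param n_clusters number of k-means centroids.
#' @param n_top_genes number of top-variance genes used for the embedding.
#' @param root_cells optional character vector of cell ids known to be early
#'   (e.g. first time point); the centroid holding most of them is the root.
#'   If `NULL` the most distal leaf of the tree is used.
#' @param marker_genes optional character vector orienting the U branch.
#' @param seed seed for k-means initialization.
#' @return data.frame with `cell_id`, `branch` (P/U/L), `pseudotime_raw`.
#' @export
infer_bifurcation <- function(norm, n_pcs = 15L, n_clusters = 10L,
                              n_top_genes = 500L, root_cells = NULL,
                              marker_genes = NULL, seed = 1L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  set.seed(seed)
  v <- apply(norm$values, 2, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, ncol(norm$values)))]
  X <- scale_clip(norm)[, top, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(X) - 1L, nrow(X) - 1L)
  pc <- stats::prcomp(X, rank. = n_pcs, center = FALSE, scale. = FALSE)
  S <- pc$x
  km <- stats::kmeans(S, centers = n_clusters, nstart = 10L, iter.max = 100L)
  C <- km$centers
  D <- as.matrix(stats::dist(C))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  deg <- igraph::degree(tree)
  td <- igraph::distances(tree)

  # root centroid
  if (!is.null(root_cells)) {
    hits <- tabulate(km$cluster[rownames(norm$values) %in% root_cells],
                     nbins = n_clusters)
    root <- which.max(hits)
  } else {
    leaves <- which(deg == 1L)
    root <- leaves[which.max(apply(td[leaves, , drop = FALSE], 1, max))]
  }
  d_root <- td[root, ]

  branch_nodes <- which(deg >= 3L)
  cl <- km$cluster
  cell_branch <- rep("P", nrow(S))

  # pseudotime: geodesic to centroid + signed projection on adjacent edge
  pt <- d_root[cl]
  adj <- igraph::as_adjacency_matrix(tree, sparse = FALSE) > 0
  for (k in seq_len(n_clusters)) {
    idx <- which(cl == k)
    if (!length(idx)) next
    nbs <- which(adj[k, ])
    if (!length(nbs)) next
    best_proj <- rep(0, length(idx))
    best_abs <- rep(-Inf, length(idx))
    for (nb in nbs) {
      e <- C[nb, ] - C[k, ]
      len <- sqrt(sum(e^2))
      if (len == 0) next
      u <- e / len
      proj <- as.vector((S[idx, , drop = FALSE] -
                           matrix(C[k, ], length(idx), ncol(C), byrow = TRUE)) %*% u)
      proj <- pmin(pmax(proj, 0), len / 2)
      sgn <- if (d_root[nb] > d_root[k]) 1 else -1
      upd <- proj > best_abs
      best_proj[upd] <- sgn * proj[upd]
      best_abs[upd] <- proj[upd]
    }
    pt[idx] <- pt[idx] + best_proj
  }
  pt <- pt - min(pt)

  # branch assignment. The MST attests that a bifurcation exists (a degree
  # >= 3 node); the actual cell-level split is carried out with a
  # discriminant direction between the two late-cell clusters, because
  # centroid-level subtree membership is too coarse near the junction where
  # the two arms are still close together. The discriminant is
  # orthogonalized against the local pseudotime direction so that a cell's
  # position along the trajectory cannot push it towards either arm, and
  # the branch time is estimated as the onset of spread of the discriminant
  # scores (falling back to the branch node's geodesic time).
  if (length(branch_nodes) == 0L) {
    warning("no branch point found in the trajectory tree; all cells labeled P")
  } else {
    bp <- branch_nodes[which.min(d_root[branch_nodes])]
    t_bp <- d_root[bp] - min(d_root[cl])
    late <- which(pt >= stats::quantile(pt, 0.7))
    km2 <- stats::kmeans(S[late, , drop = FALSE], centers = 2L, nstart = 10L)
    w <- km2$centers[1, ] - km2$centers[2, ]
    # temporal direction: per-PC slope of a linear fit against pseudotime
    v <- as.vector(stats::cov(S, pt)) / stats::var(pt)
    v <- v / sqrt(sum(v^2))
    w <- w - sum(w * v) * v
    if (sqrt(sum(w^2)) > 1e-8) {
      w <- w / sqrt(sum(w^2))
      score <- as.vector(S %*% w)
      # The branch time is estimated from the spread of the score along
      # pseudotime: the score is centered on its running (per-bin) median
      # so trajectory curvature cannot push cells towards either arm, and
      # sd(resid)^2 ~ base^2 + (gap/2)^2 once the arms separate, so the
      # de-noised gap of the separated bins is extrapolated linearly back
      # to its x-intercept. A small ensemble of binnings stabilizes the
      # intercept; the MST branch node time is the fallback.
      tb_one <- function(nb) {
        o <- order(pt)
        bin <- integer(length(pt))
        bin[o] <- ceiling(seq_along(o) * nb / length(o))
        ctr <- vapply(seq_len(nb), function(b) stats::median(score[bin == b]),
                      numeric(1))
        resid <- score - ctr[bin]
        sdw <- vapply(seq_len(nb), function(b) stats::sd(resid[bin == b]),
                      numeric(1))
        ptmid <- vapply(seq_len(nb), function(b) stats::median(pt[bin == b]),
                        numeric(1))
        base <- stats::median(sdw[seq_len(nb %/% 4)])
        big <- which(sdw > 1.5 * base)
        if (length(big) < 3L) return(NA_real_)
        g <- sqrt(pmax(sdw[big]^2 - base^2, 0))
        fit <- stats::lm.fit(cbind(1, ptmid[big]), g)
        if (fit$coefficients[2] <= 0) return(NA_real_)
        max(0, -fit$coefficients[1] / fit$coefficients[2])
      }
      tbs <- stats::na.omit(vapply(c(16L, 20L, 24L), tb_one, numeric(1)))
      t_b <- if (length(tbs)) stats::median(tbs) else t_bp
      nb <- 20L
      o <- order(pt)
      bin <- integer(length(pt))
      bin[o] <- ceiling(seq_along(o) * nb / length(o))
      ctr <- vapply(seq_len(nb), function(b) stats::median(score[bin == b]),
                    numeric(1))
      resid <- score - ctr[bin]
      post <- which(pt > t_b)
      if (length(post) >= 10L) {
        cell_branch[post] <- ifelse(resid[post] > 0, "U", "L")
        # iterative refinement: track each arm's score curve along
        # pseudotime by kernel regression of the current members and
        # reassign to the nearer curve
        h <- diff(range(pt)) / 8
        for (it in 1:3) {
          cu <- post[cell_branch[post] == "U"]
          cL <- post[cell_branch[post] == "L"]
          if (length(cu) < 5L || length(cL) < 5L) break
          KU <- exp(-0.5 * (outer(pt[post], pt[cu], "-") / h)^2)
          KL <- exp(-0.5 * (outer(pt[post], pt[cL], "-") / h)^2)
          mU <- (KU %*% score[cu]) / pmax(rowSums(KU), 1e-12)
          mL <- (KL %*% score[cL]) / pmax(rowSums(KL), 1e-12)
          cell_branch[post] <- ifelse(
            abs(score[post] - mU) < abs(score[post] - mL), "U", "L")
        }
      }
    }
  }

  # orient U as the branch with higher mean marker expression
  if (!is.null(marker_genes) && all(c("U", "L") %in% cell_branch)) {
    mk <- intersect(marker_genes, colnames(norm$values))
    if (length(mk)) {
      mu_u <- mean(norm$values[cell_branch == "U", mk, drop = FALSE])
      mu_l <- mean(norm$values[cell_branch == "L", mk, drop = FALSE])
      if (mu_l > mu_u) {
        cell_branch <- c(P = "P", U = "L", L = "U")[cell_branch]
      }
    }
  }
  data.frame(cell_id = rownames(norm$values), branch = unname(cell_branch),
             pseudotime_raw = as.numeric(pt), stringsAsFactors = FALSE)
}
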