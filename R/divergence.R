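# Kernel-smoothed per-branch expression curves along stretched pseudotime
# and detection of the pseudotime point at which a gene's expression
# diverges between branches, with the requirement that the divergence is
# maintained until the end of pseudotime.

#' Smooth per-branch expression curves along stretched pseudotime
#'
#' Nadaraya-Watson kernel regression (Gaussian kernel) of log-normalized
#' expression onto a shared grid spanning \[0, 100\], one curve per branch.
#' Grid points with no cell within three bandwidths are flagged as
#' unsupported and are excluded from downstream tail checks.
#'
#' @param norm a `normalized_matrix`.
#' @param meta data.frame with `cell_id`, `branch`, `pseudotime_stretched`.
#' @param genes gene ids to smooth (default: all).
#' @param grid_size number of evenly spaced grid points over \[0, 100\].
#' @param bandwidth Gaussian kernel bandwidth in stretched-pseudotime units.
#' @param branches branches to smooth (default U and L; add "P" if wanted).
#' @param min_cells minimum number of cells per branch.
#' @return object of class `branch_curves`: list with `grid`, `curves`
#'   (named list of grid x genes matrices), `supported` (named list of
#'   logicals per grid point), `bandwidth`.
#' @export
smooth_branch_curves <- function(norm, meta, genes = NULL, grid_size = 100L,
                                 bandwidth = 10, branches = c("U", "L"),
                                 min_cells = 20L) {
  stopifnot(inherits(norm, "normalized_matrix"), bandwidth > 0, grid_size >= 2L)
  if (is.null(genes)) genes <- colnames(norm$values)
  m <- meta[match(rownames(norm$values), meta$cell_id), ]
  grid <- seq(0, 100, length.out = grid_size)
  curves <- supported <- t_range <- list()
  for (b in branches) {
    i <- which(m$branch == b)
    if (length(i) < min_cells) {
      stop(sprintf("branch '%s' has %d cells (< %d)", b, length(i), min_cells))
    }
    tb <- m$pseudotime_stretched[i]
    K <- exp(-0.5 * (outer(grid, tb, "-") / bandwidth)^2)
    W <- K / rowSums(K)
    curves[[b]] <- W %*% norm$values[i, genes, drop = FALSE]
    supported[[b]] <- vapply(grid, function(g) any(abs(tb - g) <= 3 * bandwidth),
                             logical(1))
    t_range[[b]] <- range(tb)
  }
  structure(list(grid = grid, curves = curves, supported = supported,
                 t_range = t_range, bandwidth = bandwidth),
            class = "branch_curves")
}

#' Detect the divergence point of a gene between two branches
#'
#' Let `d(t) = curve_U(t) - curve_L(t)` on the supported grid. In the
#' default `"strict"` mode the divergence time `t*` is the earliest grid
#' point `t0` such that `|d(t)| >= delta` and `sign(d(t))` is constant for
#' all supported grid points from `t0` through the end of the grid; a gene
#' with no such point is called non-persistent. `t*` in this mode is the
#' time at which the gap reaches `delta`, so it is systematically later than
#' the onset of divergence by about `delta / slope` for a ramp-shaped gap.
#'
#' The `"sign-tail"` mode estimates the onset instead: the earliest `t0`
#' such that `sign(d)` is constant and non-zero on the whole tail and the
#' gap reaches `delta` somewhere on that tail. Both modes reject genes whose
#' curves cross back before the end of pseudotime.
#'
#' @param curves a [smooth_branch_curves()] result containing U and L.
#' @param delta minimum gap in log-expression units (> 0).
#' @param mode `"strict"` (gap >= delta on the whole tail) or `"sign-tail"`
#'   (constant sign on the tail, gap reaching delta).
#' @param genes gene ids to call (default: all smoothed genes).
#' @return data.frame with gene_id, favored_branch (U/L/none), t_star
#'   (NA when none), persistent, max_gap.
#' @export
detect_divergence <- function(curves, delta = 0.25,
                              mode = c("strict", "sign-tail"), genes = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(curves, "branch_curves"))
  if (delta <= 0) stop("delta must be > 0")
  if (!all(c("U", "L") %in% names(curves$curves))) {
    stop("curves must contain both U and L branches")
  }
  if (is.null(genes)) genes <- colnames(curves$curves$U)
  keep <- curves$supported$U & curves$supported$L
  # divergence between branches is only defined where both branches carry
  # cells: kernel extrapolation beyond a branch's own data range is flat
  # and would let the scan run into unobservable pseudotime
  if (!is.null(curves$t_range)) {
    lo <- max(curves$t_range$U[1], curves$t_range$L[1])
    hi <- min(curves$t_range$U[2], curves$t_range$L[2])
    keep <- keep & curves$grid >= lo & curves$grid <= hi
  }
  grid <- curves$grid[keep]
  DU <- curves$curves$U[keep, genes, drop = FALSE]
  DL <- curves$curves$L[keep, genes, drop = FALSE]
  G <- length(grid)
  call_one <- function(d) {
    if (mode == "strict") {
      ok <- abs(d) >= delta
      s <- sign(d)
      j <- G
      if (!ok[G]) return(list(t = NA_real_, fav = "none", gap = NA_real_))
      while (j > 1 && ok[j - 1] && s[j - 1] == s[G]) j <- j - 1
      list(t = grid[j], fav = if (s[G] > 0) "U" else "L",
           gap = max(abs(d[j:G])))
    } else {
      s <- sign(d)
      if (s[G] == 0) return(list(t = NA_real_, fav = "none", gap = NA_real_))
      j <- G
      while (j > 1 && s[j - 1] == s[G]) j <- j - 1
      gap <- max(abs(d[j:G]))
      if (gap < delta) return(list(t = NA_real_, fav = "none", gap = NA_real_))
      # onset refinement: least-squares fit of a smoothed ramp
      # beta * E[(t - t0)+ * K_bw] (a Gaussian-convolved hinge, matching
      # what the kernel smoother does to a ramp-shaped gap); the raw
      # suffix start is inflated by the long sign runs of
      # kernel-correlated noise
      ds <- s[G] * d
      bw <- curves$bandwidth
      # candidate onsets may precede the observable window (the two fates
      # only exist after the split): the ramp's extrapolated start is still
      # identified by its intercept/slope within the window
      step <- if (G > 1) grid[2] - grid[1] else 1
      cand_t <- seq(max(0, grid[1] - 2 * bw), grid[G - 2L], by = step)
      best_t <- grid[j]; best_rss <- Inf
      for (cand in cand_t) {
        u <- grid - cand
        h <- u * stats::pnorm(u / bw) + bw * stats::dnorm(u / bw)
        beta <- sum(ds * h) / sum(h^2)
        if (beta <= 0) next
        rss <- sum((ds - beta * h)^2)
        if (rss < best_rss) { best_rss <- rss; best_t <- cand }
      }
      list(t = best_t, fav = if (s[G] > 0) "U" else "L", gap = gap)
    }
  }
  res <- lapply(seq_along(genes), function(g) call_one(DU[, g] - DL[, g]))
  data.frame(
    gene_id = genes,
    favored_branch = vapply(res, `[[`, character(1), "fav"),
    t_star = vapply(res, `[[`, numeric(1), "t"),
    persistent = !is.na(vapply(res, `[[`, numeric(1), "t")),
    max_gap = vapply(res, `[[`, numeric(1), "gap"),
    stringsAsFactors = FALSE)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file, one gene symbol per line; blank lines and
#'   `#`-comments are ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Order persistent divergence calls within annotated gene lists
#'
#' For each named gene list (e.g. transcription factors, secretome), keeps
#' the genes with persistent divergence calls and orders them by increasing
#' divergence time — the machine-readable analogue of plotting
#' branch-specific genes at their divergence points.
#'
#' @param calls a [detect_divergence()] result.
#' @param gene_lists named list of character vectors.
#' @return named list of data.frames (gene_id, favored_branch, t_star,
#'   max_gap), each sorted by t_star ascending.
#' @export
annotate_gene_sets <- function(calls, gene_lists) {
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)))
  lapply(stats::setNames(names(gene_lists), names(gene_lists)), function(nm) {
    genes <- intersect(gene_lists[[nm]], calls$gene_id)
    if (!length(genes)) {
      warning(sprintf("gene list '%s' has no overlap with the data", nm))
      return(calls[0, c("gene_id", "favored_branch", "t_star", "max_gap")])
    }
    sub <- calls[calls$gene_id %in% genes & calls$persistent, , drop = FALSE]
    sub <- sub[order(sub$t_star, sub$gene_id),
               c("gene_id", "favored_branch", "t_star", "max_gap")]
    rownames(sub) <- NULL
    sub
  })
}
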