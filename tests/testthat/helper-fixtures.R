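# Shared fixtures (cached per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small but complete simulated dataset shared across module tests
shared_sim <- function() {
  cached("shared_sim", simulate_bifurcation(
    sim_config(n_cells = 800, n_genes = 300, mito_gene_count = 10,
               frac_branch_genes = 0.3, effect_size = 1.0, seed = 101)))
}

shared_norm <- function() {
  cached("shared_norm", {
    sim <- shared_sim()
    qc <- qc_filter(sim$counts, qc_thresholds(apply_mito_filter = FALSE))
    normalize_log(qc$counts)
  })
}

truth_meta <- function(sim) {
  data.frame(cell_id = sim$meta$cell_id, branch = sim$meta$branch_true,
             pseudotime_stretched = sim$meta$t_true,
             stringsAsFactors = FALSE)
}

# tiny hand-built count matrix
toy_counts <- function(values, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(values)))
  dimnames(values) <- list(cells, genes)
  count_matrix(values)
}

# construct a branch_curves object directly from gap curves
make_curves <- function(dU, dL, grid = NULL, bandwidth = 10) {
  dU <- as.matrix(dU); dL <- as.matrix(dL)
  if (is.null(colnames(dU))) {
    colnames(dU) <- colnames(dL) <- sprintf("g%d", seq_len(ncol(dU)))
  }
  if (is.null(grid)) grid <- seq(0, 100, length.out = nrow(dU))
  structure(list(grid = grid, curves = list(U = dU, L = dL),
                 supported = list(U = rep(TRUE, length(grid)),
                                  L = rep(TRUE, length(grid))),
                 t_range = NULL, bandwidth = bandwidth),
            class = "branch_curves")
}

# --- independent oracles ------------------------------------------------

# brute-force BH: q_(i) = min over ranks j >= i of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    # min over all j with rank >= rank_i of p_(j) * m / j
    q[i] <- min(1, min(p[o][rank_i:m] * m / (rank_i:m)))
  }
  q
}

# upper-tail hypergeometric probability by explicit combinatorial sums
hyper_oracle <- function(ov, K, N, n) {
  js <- ov:min(K, n)
  if (ov > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# connected components by recursive flood fill (8-connectivity)
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  sizes <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE; sz <- 0L
    while (length(stack)) {
      px <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      sz <- sz + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- px[1] + di; jj <- px[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  list(count = count, sizes = sort(sizes))
}

# strict-mode divergence call by exhaustive suffix enumeration
divergence_oracle_strict <- function(d, grid, delta) {
  G <- length(d)
  for (i in seq_len(G)) {
    tail <- d[i:G]
    if (all(abs(tail) >= delta) && length(unique(sign(tail))) == 1L) {
      return(list(t = grid[i], fav = if (sign(tail[1]) > 0) "U" else "L"))
    }
  }
  list(t = NA_real_, fav = "none")
}

# multi-Otsu by naive partition search: recompute class stats per partition
otsu_oracle <- function(v, n_classes, nbins) {
  breaks <- seq(0, 1, length.out = nbins + 1)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), nbins),
                nbins = nbins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bcv <- function(cuts) {
    edges <- c(0, cuts, nbins)
    tot <- 0
    mu <- sum(h * mids) / sum(h)
    for (k in seq_len(length(edges) - 1)) {
      sel <- (edges[k] + 1):edges[k + 1]
      wk <- sum(h[sel]) / sum(h)
      if (wk > 0) tot <- tot + wk * (sum(h[sel] * mids[sel]) / sum(h[sel]) - mu)^2
    }
    tot
  }
  combos <- utils::combn(nbins - 1, n_classes - 1)
  vals <- apply(combos, 2, bcv)
  breaks[combos[, which.max(vals)] + 1]
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# 3 well-separated Poisson clusters as a count matrix
make_cluster_counts <- function(n_per, n_genes, seed) {
  set.seed(seed)
  base <- matrix(stats::rlnorm(3 * n_genes, 0, 0.5), 3, n_genes)
  marker <- matrix(1, 3, n_genes)
  idx <- split(seq_len(n_genes), rep(1:3, length.out = n_genes))
  for (k in 1:3) marker[k, idx[[k]]] <- 6
  rates <- base * marker
  lab <- rep(c("A", "B", "C"), each = n_per)
  mu <- rates[rep(1:3, each = n_per), ]
  cnt <- matrix(stats::rpois(length(mu), mu * 3), nrow(mu), ncol(mu))
  dimnames(cnt) <- list(sprintf("cell%03d_s%d", seq_len(nrow(cnt)), seed),
                        sprintf("G%03d", seq_len(n_genes)))
  list(counts = cnt, labels = lab)
}
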