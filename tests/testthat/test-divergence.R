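test_that("kernel smoothing reproduces constants, lines and limits", {
  set.seed(4)
  n <- 200
  t <- runif(n, 0, 100)
  br <- rep(c("U", "L"), each = n / 2)
  vals <- cbind(const = rep(2.5, n), line = 1 + 0.03 * t)
  norm <- structure(list(values = vals, transform = "log-normalized",
                         size_factors = rep(1, n), target_sum = 1e4,
                         mito = c(FALSE, FALSE)),
                    class = "normalized_matrix")
  rownames(norm$values) <- sprintf("c%d", 1:n)
  meta <- data.frame(cell_id = rownames(norm$values), branch = br,
                     pseudotime_stretched = t)
  cv <- smooth_branch_curves(norm, meta, grid_size = 50, bandwidth = 10)
  expect_equal(unname(as.vector(cv$curves$U[, "const"])), rep(2.5, 50))
  # noiseless line: compare against a direct (loop-written) kernel average
  grid <- cv$grid
  tu <- t[br == "U"]
  oracle <- vapply(grid, function(g) {
    w <- exp(-0.5 * ((g - tu) / 10)^2)
    sum(w * (1 + 0.03 * tu)) / sum(w)
  }, numeric(1))
  expect_equal(unname(as.vector(cv$curves$U[, "line"])), oracle,
               tolerance = 1e-12)
  # interior points track the line itself
  interior <- grid > 20 & grid < 80
  expect_lt(max(abs(cv$curves$U[interior, "line"] -
                      (1 + 0.03 * grid[interior]))), 0.05)
  # infinite-bandwidth limit: the global branch mean everywhere
  cv_inf <- smooth_branch_curves(norm, meta, grid_size = 20, bandwidth = 1e6)
  expect_equal(unname(as.vector(cv_inf$curves$L[, "line"])),
               rep(mean((1 + 0.03 * t)[br == "L"]), 20), tolerance = 1e-6)
  expect_error(smooth_branch_curves(norm, meta[1:30, ], min_cells = 20),
               "cells")
})

test_that("strict detect_divergence equals the suffix-enumeration oracle", {
  set.seed(12)
  G <- 60
  grid <- seq(0, 100, length.out = G)
  for (rep in 1:40) {
    d <- cumsum(rnorm(G, 0, 0.2))           # random walk gap
    curves <- make_curves(matrix(d, G, 1), matrix(0, G, 1), grid = grid)
    for (delta in c(0.1, 0.3)) {
      got <- detect_divergence(curves, delta = delta, mode = "strict")
      exp_ <- divergence_oracle_strict(d, grid, delta)
      expect_equal(got$t_star, exp_$t, info = sprintf("rep %d", rep))
      expect_equal(got$favored_branch, exp_$fav)
      expect_equal(got$persistent, !is.na(exp_$t))
    }
  }
})

test_that("divergence calls respect delta-monotonicity and U/L symmetry", {
  set.seed(13)
  G <- 80
  grid <- seq(0, 100, length.out = G)
  ramp <- pmax(grid - 45, 0) / 55 * 1.2
  d <- ramp + rnorm(G, 0, 0.03)
  cu <- make_curves(matrix(d, G, 1), matrix(0, G, 1), grid = grid)
  deltas <- c(0.05, 0.2, 0.4, 0.8)
  ts <- vapply(deltas, function(dl)
    detect_divergence(cu, delta = dl, mode = "strict")$t_star, numeric(1))
  expect_true(all(diff(ts) >= 0))
  # swapping U and L flips the favored branch, not t*
  sw <- make_curves(matrix(0, G, 1), matrix(d, G, 1), grid = grid)
  a <- detect_divergence(cu, delta = 0.2)
  b <- detect_divergence(sw, delta = 0.2)
  expect_equal(a$t_star, b$t_star)
  expect_equal(a$favored_branch, "U")
  expect_equal(b$favored_branch, "L")
  # identical curves are never persistent; delta must be positive
  same <- make_curves(matrix(1, G, 1), matrix(1, G, 1), grid = grid)
  expect_false(detect_divergence(same, delta = 0.2)$persistent)
  expect_error(detect_divergence(cu, delta = 0), "delta")
})

test_that("a gap that crosses back before the end is not persistent", {
  G <- 100
  grid <- seq(0, 100, length.out = G)
  # diverges at 40, crosses back at 80 and stays near zero afterwards
  d <- ifelse(grid < 40, 0,
              ifelse(grid < 80, (grid - 40) / 40 * 1.5, -(grid - 80) / 20 * 0.1))
  cu <- make_curves(matrix(d, G, 1), matrix(0, G, 1), grid = grid)
  expect_false(detect_divergence(cu, delta = 0.25, mode = "strict")$persistent)
  # the same shape held to the end is persistent
  d2 <- ifelse(grid < 40, 0, (grid - 40) / 60) * 1.5
  cu2 <- make_curves(matrix(d2, G, 1), matrix(0, G, 1), grid = grid)
  call2 <- detect_divergence(cu2, delta = 0.25, mode = "strict")
  expect_true(call2$persistent)
  expect_equal(call2$favored_branch, "U")
})

test_that("sign-tail mode estimates the onset of a planted ramp", {
  sim <- simulate_bifurcation(
    sim_config(n_cells = 2500, n_genes = 160, mito_gene_count = 10,
               frac_branch_genes = 0.8, divergence_times = 50,
               effect_size = 2, nb_dispersion = 0.1, seed = 21))
  norm <- normalize_log(qc_filter(
    sim$counts,
    qc_thresholds(min_genes = 20, apply_mito_filter = FALSE))$counts)
  meta <- truth_meta(sim)
  tg <- sim$truth$gene
  genes <- tg$gene_id[tg$is_branch_gene]
  expect_gte(length(genes), 100)
  curves <- smooth_branch_curves(norm, meta, genes = genes)
  calls <- detect_divergence(curves, delta = 0.25, mode = "sign-tail")
  err <- abs(calls$t_star - tg$t_star[match(calls$gene_id, tg$gene_id)])
  expect_lte(median(err, na.rm = TRUE), 5)
  fav_true <- tg$favored[match(calls$gene_id, tg$gene_id)]
  expect_gte(mean(calls$favored_branch == fav_true, na.rm = TRUE), 0.95)
})

test_that("annotate_gene_sets orders persistent calls by divergence time", {
  calls <- data.frame(
    gene_id = c("tf_late", "tf_early", "tf_crossed", "other"),
    favored_branch = c("U", "L", "none", "U"),
    t_star = c(70, 30, NA, 50),
    persistent = c(TRUE, TRUE, FALSE, TRUE),
    max_gap = c(1, 2, NA, 1))
  out <- annotate_gene_sets(
    calls, list(tf = c("tf_early", "tf_late", "tf_crossed")))
  expect_equal(out$tf$gene_id, c("tf_early", "tf_late"))
  expect_equal(out$tf$t_star, c(30, 70))
  expect_warning(res <- annotate_gene_sets(calls, list(none = "absent")),
                 "no overlap")
  expect_equal(nrow(res$none), 0L)
})
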