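test_that("bh_adjust equals the brute-force BH formula", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone in p
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_equal(bh_adjust(c(0.01, NA, 0.5)),
               c(bh_adjust(c(0.01, 0.5))[1], NA, bh_adjust(c(0.01, 0.5))[2]))
})

test_that("avg_logfc has the documented symmetry and closed form", {
  set.seed(3)
  n <- 60
  br <- rep(c("U", "L"), each = n / 2)
  delta <- 0.8
  x <- rnorm(n / 2)
  vals <- cbind(null = rep(x, 2),                     # identical branch means
                shifted = c(x + delta, x))            # exact +delta on U
  norm <- structure(list(values = vals, transform = "log-normalized",
                         size_factors = rep(1, n), target_sum = 1e4,
                         mito = c(FALSE, FALSE)),
                    class = "normalized_matrix")
  rownames(norm$values) <- sprintf("c%d", 1:n)
  meta <- data.frame(cell_id = rownames(norm$values), branch = br)
  lfc <- avg_logfc(norm, meta)
  expect_equal(unname(lfc["null"]), 0)
  # a +delta natural-log shift reads as delta/log(2) on the log2 scale
  expect_equal(unname(lfc["shifted"]), delta / log(2))
  # swapping labels flips the sign, not the magnitude
  meta2 <- meta
  meta2$branch <- c(U = "L", L = "U")[meta$branch]
  expect_equal(avg_logfc(norm, meta2), -lfc)
  expect_error(avg_logfc(norm, data.frame(cell_id = meta$cell_id,
                                          branch = "U")), "both U and L")
})

test_that("the branch LR test behaves like a nested-model test", {
  sim <- shared_sim()
  norm <- shared_norm()
  meta <- truth_meta(sim)
  res <- fit_branch_test(norm, meta)
  expect_true(all(res$lr_statistic >= 0))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$q, bh_adjust(res$p))
  # planted strong-effect genes are found
  tg <- sim$truth$gene
  planted <- tg$gene_id[tg$is_branch_gene & tg$t_star == 30]
  hit <- res$significant[match(planted, res$gene_id)]
  expect_gte(mean(hit), 0.9)
  # invariance to U/L relabeling except for the logFC sign
  meta_sw <- meta
  meta_sw$branch <- c(P = "P", U = "L", L = "U")[meta$branch]
  res_sw <- fit_branch_test(norm, meta_sw)
  expect_equal(res_sw$lr_statistic, res$lr_statistic, tolerance = 1e-8)
  expect_equal(res_sw$avg_logfc, -res$avg_logfc, tolerance = 1e-12)
  # zero-variance gene reports p = 1
  norm0 <- norm
  norm0$values[, 1] <- 0
  res0 <- fit_branch_test(norm0, meta)
  expect_equal(res0$p[1], 1)
})

test_that("negative-binomial family agrees with gaussian on a strong gene", {
  sim <- shared_sim()
  norm <- shared_norm()
  meta <- truth_meta(sim)
  tg <- sim$truth$gene
  pick <- c(tg$gene_id[tg$is_branch_gene][1:3],
            tg$gene_id[!tg$is_branch_gene][1:3])
  sub <- norm
  sub$values <- norm$values[, pick]
  qc <- qc_filter(sim$counts, qc_thresholds(apply_mito_filter = FALSE))
  res_nb <- fit_branch_test(sub, meta, family = "negbin", counts = qc$counts)
  expect_true(all(res_nb$q[1:3] < 0.05))
  expect_true(all(res_nb$lr_statistic >= 0))
})

test_that("filter_branch_genes uses strict inequalities", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    q = c(0.04, 0.04, 0.05, 0.01),
                    avg_logfc = c(0.31, 0.30, 0.5, -0.6))
  expect_setequal(filter_branch_genes(res), c("a", "d"))
})

test_that("kinetic clustering handles duplicates and degenerate cuts", {
  set.seed(8)
  G <- 50
  shapes <- sapply(1:12, function(i) sin(seq(0, 3, length.out = G) + i / 2))
  cu <- shapes + matrix(rnorm(G * 12, 0, 0.01), G)
  colnames(cu) <- sprintf("g%d", 1:12)
  cl_curves <- make_curves(cu, -cu)
  genes <- colnames(cl_curves$curves$U)
  # a duplicated curve lands in the duplicate's cluster
  cu2 <- cbind(cu, dup = cu[, 1])
  curves2 <- make_curves(cu2, -cu2)
  cl <- kinetic_clusters(curves2, colnames(cu2), k = 4)
  expect_equal(unname(cl["dup"]), unname(cl[1]))
  # k = 1 puts everything together
  expect_true(all(kinetic_clusters(cl_curves, genes, k = 1) == 1L))
  expect_error(kinetic_clusters(cl_curves, genes[1:3], k = 6), "at least")
})
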