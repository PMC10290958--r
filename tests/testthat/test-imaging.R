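test_that("greyscale conversion handles grey, RGB and 8-bit inputs", {
  g <- matrix(runif(20), 4, 5)
  expect_equal(to_greyscale(g), g)
  white <- array(1, dim = c(3, 3, 3))
  expect_true(all(to_greyscale(white) == 1))
  eightbit <- matrix(c(0, 255, 128, 64), 2, 2)
  expect_equal(to_greyscale(eightbit), eightbit / 255)
  # RGB render of a dot image counts the same as the grey original
  sim <- simulate_dot_image(12, radius_range = c(3, 4),
                            image_shape = c(80L, 80L), seed = 6)
  rgb <- array(0, dim = c(80, 80, 3))
  for (ch in 1:3) rgb[, , ch] <- sim$image * c(0.9, 1, 0.8)[ch]
  n_grey <- count_dots_image(sim$image, min_size = 10)$count
  n_rgb <- count_dots_image(rgb, min_size = 10)$count
  expect_equal(n_rgb, n_grey)
  expect_error(to_greyscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("multi-Otsu thresholds maximize between-class variance", {
  # two-level image: threshold separates the levels
  img <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  th2 <- multi_otsu_thresholds(img, n_classes = 2)
  expect_true(th2 > 0.1 && th2 < 0.9)
  mask <- multi_otsu_mask(img, n_classes = 2)
  expect_equal(mask, img > 0.5)
  # 3-class thresholds equal the naive partition-search oracle (64 bins)
  set.seed(16)
  for (i in 1:5) {
    v <- c(runif(60, 0, 0.2), runif(50, 0.4, 0.6), runif(40, 0.8, 1))
    im <- matrix(sample(v), 10, 15)
    got <- multi_otsu_thresholds(im, n_classes = 3, nbins = 64)
    want <- otsu_oracle(as.vector(im), 3, 64)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # dim speckle below the lowest threshold leaves bright components alone:
  # bright dots at 1.0, mid-intensity blobs at 0.55, background 0; the
  # darkest class absorbs 0.1-level speckle
  sim <- simulate_dot_image(8, radius_range = c(3, 4),
                            image_shape = c(64L, 64L), seed = 7)
  base_img <- sim$image
  base_img[2:5, 2:5] <- 0.55
  base_img[60:63, 60:63] <- 0.55
  dim_img <- base_img
  bg <- dim_img == 0
  set.seed(17)
  dim_img[which(bg)[sample(sum(bg), 150)]] <- 0.1
  m1 <- multi_otsu_mask(base_img, n_classes = 3)
  m2 <- multi_otsu_mask(dim_img, n_classes = 3)
  expect_equal(flood_fill_count(m2)$sizes, flood_fill_count(m1)$sizes)
  expect_error(multi_otsu_thresholds(matrix(0.5, 5, 5)), "constant")
})

test_that("connected components agree with a flood-fill oracle", {
  sq <- matrix(FALSE, 6, 6); sq[2:4, 2:4] <- TRUE
  cc <- connected_components(sq)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$size, 9L)
  expect_equal(c(cc$centroid_row, cc$centroid_col), c(3, 3))
  expect_equal(c(cc$bbox_rmin, cc$bbox_rmax, cc$bbox_cmin, cc$bbox_cmax),
               c(2L, 4L, 2L, 4L))
  # diagonal touch merges under 8-connectivity
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(nrow(connected_components(diag2)), 1L)
  # random masks vs oracle
  set.seed(18)
  for (i in 1:6) {
    mask <- matrix(runif(32 * 32) < 0.35, 32, 32)
    got <- connected_components(mask)
    want <- flood_fill_count(mask)
    expect_equal(nrow(got), want$count)
    expect_equal(sort(got$size), want$sizes)
  }
  empty <- connected_components(matrix(FALSE, 4, 4))
  expect_equal(nrow(empty), 0L)
})

test_that("the knee gate isolates outliers and falls back gracefully", {
  # [5,5,5,5,200]: chord from (1,5) to (5,200); knee at the corner
  expect_equal(elbow_max_size(c(5, 5, 5, 5, 200), hard_max = 1000), 5)
  expect_lt(elbow_max_size(c(5, 5, 5, 5, 200), hard_max = 1000), 200)
  # degenerate: all equal or too few components -> hardcoded maximum
  expect_equal(elbow_max_size(rep(7, 10), hard_max = 1234), 1234)
  expect_message(out <- elbow_max_size(c(3, 4), hard_max = 99), "fewer than 3")
  expect_equal(out, 99)
  # scale equivariance when the knee is accepted
  s <- c(10, 11, 12, 11, 10, 400)
  expect_equal(elbow_max_size(2 * s, hard_max = 1e5),
               2 * elbow_max_size(s, hard_max = 1e5))
  # near-linear curves are not gated
  expect_equal(elbow_max_size(seq(10, 30, by = 2), hard_max = 777), 777)
})

test_that("count_dots applies its gates inclusively", {
  comps <- data.frame(size = c(5, 20, 100, 2000, 2001))
  expect_equal(count_dots(comps, min_size = 20, max_size = 2000), 3L)
  expect_equal(count_dots(comps[0, , drop = FALSE], 20, 2000), 0L)
  # a merged blob above the knee gate is excluded end-to-end
  sim <- simulate_dot_image(15, radius_range = c(3, 4),
                            image_shape = c(160L, 160L), seed = 8)
  blob <- sim$image
  expect_equal(sum(blob[130:157, 130:157]), 0)  # corner is clear of dots
  blob[132:155, 132:155] <- 1   # one huge merged blob
  res <- count_dots_image(blob, min_size = 10, max_size = 5000)
  expect_equal(res$count, 15L)
})

test_that("counting is exact on planted images and translation-invariant", {
  sim <- simulate_dot_image(18, radius_range = c(3, 5),
                            image_shape = c(110L, 110L), speck_count = 25,
                            seed = 9)
  res <- count_dots_image(sim$image, min_size = 15)
  expect_equal(res$count, 18L)
  # translate by (1, 1): the generator leaves a 1 px margin at the borders
  dots <- simulate_dot_image(18, radius_range = c(3, 5),
                             image_shape = c(110L, 110L), seed = 9)
  shifted <- matrix(0, 110, 110)
  shifted[2:110, 2:110] <- dots$image[1:109, 1:109]
  expect_equal(sum(shifted), sum(dots$image))
  expect_equal(count_dots_image(shifted, min_size = 15)$count,
               count_dots_image(dots$image, min_size = 15)$count)
})

test_that("PGM round-trips images as plain text", {
  img <- matrix(round(runif(30) * 255) / 255, 5, 6)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, path)
  back <- read_pgm(path)
  expect_equal(back, img, tolerance = 1 / 255)
  expect_equal(dim(back), dim(img))
})
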