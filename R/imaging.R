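# Nuclei dot counting: greyscale conversion, multi-Otsu background removal,
# 8-connectivity connected components, knee-point maximum-size gating with a
# hardcoded cap, and the final count.

#' Convert an image to greyscale in \[0, 1\]
#'
#' 3-channel arrays are collapsed by the Rec. 709 luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B); values above 1 are assumed to be 8-bit
#' and divided by 255.
#'
#' @param image a 2-D matrix or a rows x cols x 3 array.
#' @return matrix with values in \[0, 1\].
#' @export
to_greyscale <- function(image) {
  if (length(image) == 0) stop("empty image")
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] != 3L) stop("expected 3 channels")
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
      0.0722 * image[, , 3]
  }
  if (!is.matrix(image)) stop("expected a 2-D intensity grid")
  if (any(!is.finite(image))) stop("image contains non-finite values")
  mx <- max(image)
  if (mx > 1) image <- image / 255
  pmin(pmax(image, 0), 1)
}

#' Multi-Otsu thresholds
#'
#' Exhaustive search for the `n_classes - 1` thresholds of an intensity
#' histogram that maximize the between-class variance
#' `sum_k w_k (mu_k - mu)^2` over `n_classes` classes.
#'
#' @param image greyscale matrix in \[0, 1\].
#' @param n_classes number of intensity classes (2-4).
#' @param nbins histogram bins.
#' @return numeric vector of `n_classes - 1` thresholds (intensity values,
#'   ascending).
#' @export
multi_otsu_thresholds <- function(image, n_classes = 3L, nbins = 256L) {
  stopifnot(n_classes >= 2L, n_classes <= 4L)
  v <- as.vector(image)
  if (length(unique(v)) < 2L) stop("constant image: no threshold exists")
  breaks <- seq(0, 1, length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), nbins),
                nbins = nbins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- h / sum(h)
  cw <- cumsum(w)              # cumulative weight up to bin i
  cm <- cumsum(w * mids)       # cumulative first moment
  # between-class variance of a class spanning bins (a, b]
  class_term <- function(a, b) {
    # a, b are bin indices, a < b; class = bins (a+1)..b
    ww <- cw[b] - if (a >= 1) cw[a] else 0
    mm <- cm[b] - if (a >= 1) cm[a] else 0
    ifelse(ww > 0, mm^2 / ww, 0)
  }
  nb <- nbins
  if (n_classes == 2L) {
    sapply_var <- vapply(seq_len(nb - 1L), function(t1)
      class_term(0L, t1) + class_term(t1, nb), numeric(1))
    t_idx <- which.max(sapply_var)
    return(breaks[t_idx + 1L])
  }
  if (n_classes == 3L) {
    best <- -Inf; bi <- c(1L, 2L)
    for (t1 in seq_len(nb - 2L)) {
      a <- class_term(0L, t1)
      t2s <- (t1 + 1L):(nb - 1L)
      tot <- a + vapply(t2s, function(t2)
        class_term(t1, t2) + class_term(t2, nb), numeric(1))
      j <- which.max(tot)
      if (tot[j] > best) { best <- tot[j]; bi <- c(t1, t2s[j]) }
    }
    return(breaks[bi + 1L])
  }
  # n_classes == 4: coarser grid keeps the search tractable
  combos <- utils::combn(nb - 1L, 3L)
  tot <- apply(combos, 2, function(ts)
    class_term(0L, ts[1]) + class_term(ts[1], ts[2]) +
      class_term(ts[2], ts[3]) + class_term(ts[3], nb))
  breaks[combos[, which.max(tot)] + 1L]
}

#' Foreground mask from multi-Otsu thresholds
#'
#' By default pixels strictly above the lowest threshold are foreground
#' (background removal discards only the darkest class); set
#' `rule = "highest"` to keep only the brightest class.
#'
#' @param image greyscale matrix in \[0, 1\].
#' @param n_classes number of intensity classes.
#' @param rule `"lowest"` (default) or `"highest"`.
#' @param nbins histogram bins.
#' @return logical matrix.
#' @export
multi_otsu_mask <- function(image, n_classes = 3L, rule = c("lowest", "highest"),
                            nbins = 256L) {
  rule <- match.arg(rule)
  th <- multi_otsu_thresholds(image, n_classes = n_classes, nbins = nbins)
  cut <- if (rule == "lowest") min(th) else max(th)
  image > cut
}

#' Connected components of a binary mask (8-connectivity)
#'
#' Two-pass row-scan labeling with union-find merging.
#'
#' @param mask logical matrix.
#' @return data.frame with component, size, centroid_row, centroid_col,
#'   bbox_rmin, bbox_rmax, bbox_cmin, bbox_cmax; zero rows for an empty
#'   mask. The label matrix is attached as attribute `"labels"`.
#' @export
connected_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      # previously scanned 8-neighbours (column-major scan)
      nb <- integer(0)
      if (i > 1L && lab[i - 1L, j] > 0L) nb <- c(nb, lab[i - 1L, j])
      if (j > 1L) {
        if (lab[i, j - 1L] > 0L) nb <- c(nb, lab[i, j - 1L])
        if (i > 1L && lab[i - 1L, j - 1L] > 0L) nb <- c(nb, lab[i - 1L, j - 1L])
        if (i < nr && lab[i + 1L, j - 1L] > 0L) nb <- c(nb, lab[i + 1L, j - 1L])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        m <- min(nb)
        lab[i, j] <- m
        for (o in nb) union2(m, o)
      }
    }
  }
  if (nxt == 0L) {
    out <- data.frame(component = integer(0), size = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      bbox_rmin = integer(0), bbox_rmax = integer(0),
                      bbox_cmin = integer(0), bbox_cmax = integer(0))
    attr(out, "labels") <- lab
    return(out)
  }
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  idx <- which(lab > 0L)
  lab[idx] <- relab[lab[idx]]
  comp <- lab[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  out <- data.frame(
    component = sort(unique(comp)),
    size = as.integer(tabulate(comp)),
    centroid_row = as.numeric(tapply(rows, comp, mean)),
    centroid_col = as.numeric(tapply(cols, comp, mean)),
    bbox_rmin = as.integer(tapply(rows, comp, min)),
    bbox_rmax = as.integer(tapply(rows, comp, max)),
    bbox_cmin = as.integer(tapply(cols, comp, min)),
    bbox_cmax = as.integer(tapply(cols, comp, max)))
  attr(out, "labels") <- lab
  out
}

#' Knee-point maximum-size threshold
#'
#' Sorts the component sizes ascending and finds the knee as the point of
#' maximum distance *below* the chord from the first to the last point (a
#' Kneedle-style elbow, sensitive to a sudden blow-up of sizes caused by
#' merged blobs). The returned threshold is the size at the knee, capped by
#' the hardcoded maximum. The knee is only trusted when its chord distance
#' exceeds `prominence` times the size range; otherwise (near-linear or
#' all-equal curves, fewer than 3 components) the hardcoded maximum is
#' returned as a logged fallback.
#'
#' The default `prominence` of 0.5 is chosen so that the intrinsic
#' convexity of a homogeneous dot population's sorted sizes (pixel count
#' grows with the square of the radius, bounding the chord deviation at
#' about 25% of the size range) never triggers the gate, while a merged
#' blob an order of magnitude above the dot sizes produces a corner with
#' deviation close to the full range.
#'
#' @param sizes integer vector of component pixel counts.
#' @param hard_max hardcoded maximum dot size (cap and fallback).
#' @param prominence minimum chord distance, as a fraction of the size
#'   range, for the knee to be accepted.
#' @return the maximum-size threshold.
#' @export
elbow_max_size <- function(sizes, hard_max = 2000, prominence = 0.5) {
  if (length(sizes) < 3L) {
    message("fewer than 3 components: falling back to the hardcoded maximum")
    return(hard_max)
  }
  s <- sort(sizes)
  n <- length(s)
  rng <- s[n] - s[1]
  if (rng == 0) {
    message("all component sizes equal: falling back to the hardcoded maximum")
    return(hard_max)
  }
  # signed vertical-distance-below-chord is proportional to the
  # perpendicular distance for a fixed chord; argmax is identical
  x <- seq_len(n)
  chord <- s[1] + (s[n] - s[1]) * (x - 1) / (n - 1)
  below <- chord - s
  k <- which.max(below)
  if (below[k] < prominence * rng) {
    return(hard_max)
  }
  min(s[k], hard_max)
}

#' Count dots from component statistics
#'
#' @param components a [connected_components()] result (or anything with a
#'   `size` column).
#' @param min_size,max_size inclusive size gates (`min_size <= size <=
#'   max_size`).
#' @return integer count.
#' @export
count_dots <- function(components, min_size = 20, max_size = 2000) {
  stopifnot(min_size > 0, max_size > 0, min_size < max_size)
  if (nrow(components) == 0L) return(0L)
  sum(components$size >= min_size & components$size <= max_size)
}

#' End-to-end dot counting on an image
#'
#' Greyscale conversion, multi-Otsu background mask, connected components,
#' sub-minimum noise removal, knee-point maximum-size gate (capped by the
#' hardcoded maximum), and the final count.
#'
#' @param image raster (matrix or 3-channel array).
#' @param n_classes multi-Otsu classes.
#' @param min_size hardcoded minimum dot size (pixels).
#' @param max_size hardcoded maximum dot size (cap for the knee gate).
#' @param use_elbow apply the knee-point maximum-size gate.
#' @param mask_rule threshold rule passed to [multi_otsu_mask()].
#' @return list with `count`, `min_size`, `max_size_effective`,
#'   `component_sizes`.
#' @export
count_dots_image <- function(image, n_classes = 3L, min_size = 20,
                             max_size = 2000, use_elbow = TRUE,
                             mask_rule = "lowest") {
  grey <- to_greyscale(image)
  mask <- multi_otsu_mask(grey, n_classes = n_classes, rule = mask_rule)
  comps <- connected_components(mask)
  kept <- comps[comps$size >= min_size, , drop = FALSE]
  eff_max <- if (use_elbow) elbow_max_size(kept$size, hard_max = max_size)
             else max_size
  n <- count_dots(comps, min_size = min_size, max_size = eff_max)
  list(count = n, min_size = min_size, max_size_effective = eff_max,
       component_sizes = comps$size)
}

#' Write a greyscale image as plain-text PGM (P2)
#'
#' ASCII portable graymap: a text-only raster interchange format readable
#' without any image library.
#'
#' @param image matrix in \[0, 1\].
#' @param path output file.
#' @param maxval quantization maximum (default 8-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 1))
  q <- round(image * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#'
#' @param path PGM file.
#' @return matrix with values in \[0, 1\].
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file")
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nr, nc, byrow = TRUE) / maxval
}
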