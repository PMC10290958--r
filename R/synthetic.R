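# Synthetic bifurcating single-cell data with planted ground truth.
#
# The generator emulates the structure of an in vitro adipogenesis time
# course: cells progress along a true pseudotime t in [0, 100]; early cells
# (t below `split_time`) form a common progenitor branch P, later cells split
# into an upper (U) and lower (L) fate. Counts are negative binomial with a
# per-cell library size and per-gene piecewise-linear baseline trend; branch
# genes carry a log-scale ramp effect on their favored branch starting at a
# planted divergence time t*.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by
#' [simulate_bifurcation()]. Defaults are the stated world of the package's
#' acceptance suite; see the methods vignette for the rationale behind each.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (including `mito_gene_count` mitochondrial
#'   genes).
#' @param frac_branch_genes fraction of genes carrying a branch-dependent
#'   effect.
#' @param divergence_times planted divergence pseudotimes t* in \[0, 100\];
#'   branch genes cycle through this list.
#' @param effect_size log-scale (natural log) mean shift reached at t = 100
#'   on the favored branch; `0` plants no branch genes.
#' @param nb_dispersion negative-binomial dispersion alpha, with
#'   variance = mu + alpha * mu^2.
#' @param libsize_lognormal_sigma sigma of the lognormal library-size
#'   distribution (mean fixed at `libsize_mean`).
#' @param libsize_mean mean library size in UMIs.
#' @param mito_gene_count number of mitochondrial ("MT-" prefixed) genes.
#' @param mito_weight total expression share of mitochondrial genes.
#' @param dediff_fraction fraction of late cells (t >= 80) relabeled to a
#'   progenitor-like state with attenuated branch effects, emulating
#'   dedifferentiation.
#' @param dediff_attenuation multiplier applied to branch effects of
#'   dedifferentiated cells.
#' @param crossing_fraction fraction of branch genes whose divergence does
#'   not persist: the gap ramps up from t*, decays back through zero at
#'   t = 90 and ends at `-0.15 * effect_size`.
#' @param split_time pseudotime below which cells are labeled P.
#' @param branch_prop_u probability that a post-split cell is assigned to U.
#' @param baseline_sd sd of the per-gene log trend knots (t = 0, 50, 100).
#' @param gene_weight_sdlog sdlog of the lognormal per-gene expression
#'   weights.
#' @param seed integer seed fixing the full output bit-for-bit.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 1000L,
                       frac_branch_genes = 0.2,
                       divergence_times = c(30, 60),
                       effect_size = 1.0,
                       nb_dispersion = 0.5,
                       libsize_lognormal_sigma = 0.3,
                       libsize_mean = 5000,
                       mito_gene_count = 10L,
                       mito_weight = 0.05,
                       dediff_fraction = 0,
                       dediff_attenuation = 0.3,
                       crossing_fraction = 0,
                       split_time = 40,
                       branch_prop_u = 0.5,
                       baseline_sd = 0.5,
                       gene_weight_sdlog = 1,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    frac_branch_genes = frac_branch_genes,
    divergence_times = divergence_times, effect_size = effect_size,
    nb_dispersion = nb_dispersion,
    libsize_lognormal_sigma = libsize_lognormal_sigma,
    libsize_mean = libsize_mean,
    mito_gene_count = as.integer(mito_gene_count),
    mito_weight = mito_weight,
    dediff_fraction = dediff_fraction,
    dediff_attenuation = dediff_attenuation,
    crossing_fraction = crossing_fraction,
    split_time = split_time, branch_prop_u = branch_prop_u,
    baseline_sd = baseline_sd, gene_weight_sdlog = gene_weight_sdlog,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 1L, cfg$n_genes >= 1L,
            cfg$nb_dispersion > 0, cfg$libsize_lognormal_sigma >= 0,
            cfg$libsize_mean > 0, cfg$mito_gene_count >= 0L,
            cfg$effect_size >= 0, cfg$split_time >= 0, cfg$split_time <= 100)
  assert_fraction(cfg$frac_branch_genes, "frac_branch_genes")
  assert_fraction(cfg$dediff_fraction, "dediff_fraction")
  assert_fraction(cfg$crossing_fraction, "crossing_fraction")
  assert_fraction(cfg$branch_prop_u, "branch_prop_u")
  if (length(cfg$divergence_times) &&
      (any(cfg$divergence_times < 0) || any(cfg$divergence_times > 100))) {
    stop("divergence_times must lie in [0, 100]")
  }
  if (cfg$frac_branch_genes > 0 && cfg$effect_size > 0 &&
      length(cfg$divergence_times) == 0L) {
    stop("frac_branch_genes > 0 requires non-empty divergence_times")
  }
  invisible(cfg)
}

# Planted log-scale gap between the favored and the other branch.
# Persistent genes: linear ramp from 0 at t* to `effect` at t = 100.
# Crossing genes: up to `effect` at the midpoint of [t*, 90], back through
# zero at 90, down to -0.15 * effect at 100.
#' @keywords internal
planted_gap <- function(t, t_star, effect, crossing = FALSE) {
  if (!crossing) {
    ifelse(t <= t_star, 0, effect * (t - t_star) / (100 - t_star))
  } else {
    mid <- (t_star + 90) / 2
    ifelse(t <= t_star, 0,
      ifelse(t <= mid, effect * (t - t_star) / (mid - t_star),
        ifelse(t <= 90, effect * (90 - t) / (90 - mid),
               -0.15 * effect * (t - 90) / 10)))
  }
}

#' Simulate a bifurcating single-cell UMI count dataset
#'
#' Draws cells along a true pseudotime in \[0, 100\] with a progenitor branch
#' splitting into two fates, negative-binomial counts with lognormal library
#' sizes, flagged mitochondrial genes, and branch genes whose favored-branch
#' mean departs from the shared baseline at a planted divergence time, the
#' gap growing monotonically thereafter (persistent genes).
#'
#' @param config a [sim_config()] object.
#' @return list with components `counts` (a [count_matrix()]), `meta`
#'   (per-cell data.frame: cell_id, depot, timepoint, branch_true, t_true,
#'   libsize_true) and `truth` (list with per-gene data.frame `gene`:
#'   gene_id, is_branch_gene, favored, t_star, archetype, crossing; plus
#'   `config`).
#' @export
simulate_bifurcation <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  nc <- config$n_cells; ng <- config$n_genes
  nm <- min(config$mito_gene_count, ng)

  gene_ids <- c(if (nm > 0L) sprintf("MT-%d", seq_len(nm)),
                sprintf("G%04d", seq_len(ng - nm)))
  mito <- startsWith(gene_ids, "MT-")

  # cells
  t_true <- stats::runif(nc, 0, 100)
  branch <- ifelse(t_true < config$split_time, "P",
                   ifelse(stats::runif(nc) < config$branch_prop_u, "U", "L"))
  branch_orig <- branch
  dediff <- rep(FALSE, nc)
  if (config$dediff_fraction > 0) {
    late <- which(t_true >= 80 & branch != "P")
    n_dd <- round(config$dediff_fraction * length(late))
    if (n_dd > 0) {
      dd <- sample(late, n_dd)
      dediff[dd] <- TRUE
      branch[dd] <- "P"
    }
  }
  libsize <- config$libsize_mean *
    exp(stats::rnorm(nc, 0, config$libsize_lognormal_sigma) -
          config$libsize_lognormal_sigma^2 / 2)

  # genes: lognormal weights, mito genes pinned to a fixed total share
  w <- stats::rlnorm(ng, 0, config$gene_weight_sdlog)
  if (nm > 0L) {
    w[mito] <- config$mito_weight / (1 - config$mito_weight) *
      sum(w[!mito]) / nm
  }
  knots <- matrix(stats::rnorm(ng * 3, 0, config$baseline_sd), ng, 3)
  knots[mito, ] <- 0  # mito share kept stable along pseudotime

  n_branch <- if (config$effect_size > 0)
    round(config$frac_branch_genes * (ng - nm)) else 0L
  candidates <- which(!mito)
  is_branch <- rep(FALSE, ng)
  favored <- rep(NA_character_, ng)
  t_star <- rep(NA_real_, ng)
  crossing <- rep(FALSE, ng)
  archetype <- rep(NA_integer_, ng)
  if (n_branch > 0L) {
    bg <- sample(candidates, n_branch)
    is_branch[bg] <- TRUE
    dt <- config$divergence_times
    idx <- seq_len(n_branch)
    favored[bg] <- c("U", "L")[((idx - 1L) %% 2L) + 1L]
    t_star[bg] <- dt[((idx - 1L) %/% 2L) %% length(dt) + 1L]
    # archetype = (favored branch, t*) combination
    archetype[bg] <- match(
      paste(favored[bg], t_star[bg]),
      as.vector(outer(c("U", "L"), dt, paste)))
    n_cross <- round(config$crossing_fraction * n_branch)
    if (n_cross > 0L) crossing[bg[seq_len(n_cross)]] <- TRUE
  }

  # per-cell per-gene mean: baseline trend x branch effect, scaled to libsize
  interp_log <- function(t) {
    # piecewise-linear interpolation of the log-trend knots at 0/50/100
    lo <- pmin(pmax(t / 50, 0), 2)
    seg <- ifelse(lo <= 1, 1L, 2L)
    frac <- lo - (seg - 1L)
    cbind(seg, frac)
  }
  sf <- interp_log(t_true)
  # log baseline: ng x nc
  logbase <- matrix(0, ng, nc)
  k1 <- knots[, 1]; k2 <- knots[, 2]; k3 <- knots[, 3]
  seg1 <- sf[, 1] == 1L
  logbase[, seg1] <- outer(k2 - k1, sf[seg1, 2]) + k1
  logbase[, !seg1] <- outer(k3 - k2, sf[!seg1, 2]) + k2

  eff <- matrix(0, ng, nc)
  if (n_branch > 0L) {
    for (g in which(is_branch)) {
      gap <- planted_gap(t_true, t_star[g], config$effect_size, crossing[g])
      on_branch <- branch_orig == favored[g]
      atten <- ifelse(dediff, config$dediff_attenuation, 1)
      eff[g, ] <- gap * on_branch * atten
    }
  }
  rate <- w * exp(logbase + eff)
  p <- sweep(rate, 2, colSums(rate), "/")
  mu <- sweep(p, 2, libsize, "*")
  counts <- matrix(
    stats::rnbinom(ng * nc, size = 1 / config$nb_dispersion, mu = as.vector(mu)),
    ng, nc)
  cell_ids <- sprintf("cell_%04d", seq_len(nc))
  depots <- sample(c("supra", "peri", "subq", "visce"), nc, replace = TRUE)
  timepoint <- cut(t_true, c(-Inf, config$split_time, 70, Inf),
                   labels = c("T1-T3", "T4", "T5"))

  cm <- count_matrix(Matrix::Matrix(t(counts), sparse = TRUE,
                                    dimnames = list(cell_ids, gene_ids)),
                     mito = mito)
  meta <- data.frame(
    cell_id = cell_ids, depot = depots, timepoint = as.character(timepoint),
    branch_true = branch, t_true = t_true, libsize_true = libsize,
    dediff = dediff, stringsAsFactors = FALSE)
  truth <- list(
    gene = data.frame(
      gene_id = gene_ids, is_branch_gene = is_branch, favored = favored,
      t_star = t_star, archetype = archetype, crossing = crossing,
      weight = w, stringsAsFactors = FALSE),
    config = config)
  list(counts = cm, meta = meta, truth = truth)
}

#' Simulate mixtures of a two-column signature
#'
#' Each output profile is `f * brown + (1 - f) * white` plus Gaussian noise,
#' truncated at zero — a fixture for [estimate_fractions()].
#'
#' @param signature data.frame with columns `gene`, `brown`, `white`
#'   (see [synthetic_signature()]).
#' @param fractions numeric vector of brown fractions in \[0, 1\].
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed integer seed.
#' @return genes x mixtures matrix with rownames from `signature$gene` and
#'   one column per fraction.
#' @export
simulate_mixture <- function(signature, fractions, noise_sd = 0, seed = 1L) {
  assert_fraction(fractions, "fractions")
  stopifnot(noise_sd >= 0, all(c("gene", "brown", "white") %in% names(signature)))
  set.seed(seed)
  prof <- sapply(fractions, function(f) {
    x <- f * signature$brown + (1 - f) * signature$white
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
    pmax(x, 0)
  })
  prof <- matrix(prof, nrow = nrow(signature),
                 dimnames = list(signature$gene,
                                 sprintf("mix_%02d", seq_along(fractions))))
  prof
}

#' Synthetic brown/white signature matrix
#'
#' Lognormal marker profiles for the two components, guaranteed distinct.
#' Ships as the default test signature; real analyses should supply a marker
#' signature of their own.
#'
#' @param n_genes number of signature genes.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `brown`, `white`.
#' @export
synthetic_signature <- function(n_genes = 100L, seed = 42L) {
  set.seed(seed)
  data.frame(
    gene = sprintf("SIG%03d", seq_len(n_genes)),
    brown = stats::rlnorm(n_genes, 0, 1),
    white = stats::rlnorm(n_genes, 0, 1),
    stringsAsFactors = FALSE)
}

#' Simulate a dot image with planted count
#'
#' Places `n_dots` non-overlapping bright discs on a dark background, plus
#' optional single-pixel "specks" (bright, but strictly smaller than any
#' minimum-dot-size gate matched to `radius_range`) and Gaussian noise.
#'
#' @param n_dots number of discs; `0` yields a blank image.
#' @param radius_range length-2 numeric, disc radii are drawn uniformly from
#'   this range.
#' @param image_shape length-2 integer (rows, cols).
#' @param speck_count number of isolated bright single pixels.
#' @param noise_sd Gaussian noise sd added to the image (clipped to \[0, 1\]).
#' @param seed integer seed.
#' @param max_tries placement attempts per object before giving up.
#' @return list with `image` (rows x cols matrix in \[0, 1\]), `truth_count`,
#'   `centers`, `radii`, and `min_dot_size` (pixel count of the smallest
#'   placed disc; specks are always strictly smaller).
#' @export
simulate_dot_image <- function(n_dots, radius_range = c(3, 6),
                               image_shape = c(128L, 128L),
                               speck_count = 0L, noise_sd = 0, seed = 1L,
                               max_tries = 500L) {
  stopifnot(n_dots >= 0, length(radius_range) == 2, radius_range[1] > 0,
            noise_sd >= 0)
  set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  img <- matrix(0, nr, nc)
  occupied <- matrix(FALSE, nr, nc)  # foreground + 1px halo
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  rowg <- row(img); colg <- col(img)
  place_disc <- function(r) {
    for (i in seq_len(max_tries)) {
      cy <- stats::runif(1, r + 2, nr - r - 1)
      cx <- stats::runif(1, r + 2, nc - r - 1)
      d2 <- (rowg - cy)^2 + (colg - cx)^2
      core <- d2 <= r^2
      halo <- d2 <= (r + 2)^2
      if (!any(occupied & halo)) {
        img[core] <<- 1
        occupied[halo] <<- TRUE
        centers <<- rbind(centers, c(cy, cx))
        radii <<- c(radii, r)
        return(TRUE)
      }
    }
    FALSE
  }
  if (n_dots > 0) {
    rs <- stats::runif(n_dots, radius_range[1], radius_range[2])
    for (r in rs) {
      if (!place_disc(r)) {
        stop("could not place ", n_dots, " non-overlapping dots in a ",
             nr, "x", nc, " image")
      }
    }
  }
  if (speck_count > 0) {
    placed <- 0L
    for (i in seq_len(max_tries * speck_count)) {
      if (placed >= speck_count) break
      y <- sample.int(nr - 2L, 1L) + 1L
      x <- sample.int(nc - 2L, 1L) + 1L
      win <- occupied[(y - 1L):(y + 1L), (x - 1L):(x + 1L)]
      if (!any(win)) {
        img[y, x] <- 1
        occupied[(y - 1L):(y + 1L), (x - 1L):(x + 1L)] <- TRUE
        placed <- placed + 1L
      }
    }
    if (placed < speck_count) stop("could not place all specks")
  }
  if (noise_sd > 0) {
    img <- pmin(pmax(img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0), 1)
  }
  min_dot_size <- if (n_dots > 0) {
    # conservative lower bound on disc pixel count at the smallest radius
    min(vapply(seq_len(n_dots), function(i) {
      sum((rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2 <= radii[i]^2)
    }, numeric(1)))
  } else NA_real_
  list(image = img, truth_count = as.integer(n_dots), centers = centers,
       radii = radii, min_dot_size = min_dot_size)
}
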