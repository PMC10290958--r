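# End-to-end orchestration: one flat config drives the stages
# qc -> trajectory -> branchtest -> divergence -> deconv -> enrich,
# writing stage outputs and a reproducibility manifest.

#' Default pipeline configuration
#'
#' One flat structured config with per-stage sections. Every default equals
#' the quoted analysis value where one exists (QC 200/9000/120000/8%,
#' q < 0.05, |logFC| > 0.3, six kinetic clusters, ten deciles, the 0-100
#' stretched-pseudotime grid).
#'
#' @param out_dir run directory for stage outputs.
#' @param seed integer seed used for every stochastic stage.
#' @param input optional path to an existing count matrix (MTX directory or
#'   CSV); when `NULL` the synthetic generator is used.
#' @param stages named logical list toggling stages.
#' @param ... overrides for individual sections (`simulate`, `qc`,
#'   `trajectory`, `branchtest`, `divergence`, `deconv`, `enrich`), each a
#'   named list merged over the defaults.
#' @return a nested list of class `run_config`.
#' @export
default_config <- function(out_dir = tempfile("adipobranch_run_"), seed = 1L,
                           input = NULL, stages = list(), ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), input = input,
    stages = utils::modifyList(
      list(qc = TRUE, trajectory = TRUE, branchtest = TRUE,
           divergence = TRUE, deconv = TRUE, enrich = TRUE), stages),
    simulate = list(n_cells = 1000L, n_genes = 600L,
                    frac_branch_genes = 0.2, effect_size = 1.0),
    qc = list(min_genes = 200L, max_genes = 9000L, max_umis = 120000L,
              max_mito = 0.08, mito_filter = TRUE, min_cells_per_gene = 3L),
    trajectory = list(n_pcs = 15L, n_clusters = 10L, n_bins = 10L),
    branchtest = list(q_max = 0.05, lfc_min = 0.3, k = 6L, spline_df = 3L,
                      family = "gaussian"),
    divergence = list(delta = 0.25, bandwidth = 10, grid = 100L,
                      mode = "strict"),
    deconv = list(signature = NULL),
    enrich = list(gmt = NULL))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (JSON round-trip)
#'
#' @param config a `run_config`.
#' @param path JSON file.
#' @return `read_config` returns the `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in order qc, trajectory, branchtest, divergence, deconv,
#' enrich; each writes its outputs under `config$out_dir` and any stage
#' error halts the run with a stage-tagged message. A `manifest.json`
#' records the package version, seed, parameters and md5 hashes of every
#' output file.
#'
#' @param config a [default_config()] object.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()

  # input
  sim <- NULL
  if (is.null(config$input)) {
    sim <- simulate_bifurcation(do.call(
      sim_config, c(config$simulate, list(seed = config$seed))))
    counts <- sim$counts
    write_counts_mtx(counts, file.path(config$out_dir, "raw_counts"))
  } else {
    counts <- read_counts(config$input)
  }

  # qc
  if (isTRUE(config$stages$qc)) {
    qc <- stage("qc", {
      th <- qc_thresholds(
        min_genes = config$qc$min_genes, max_genes = config$qc$max_genes,
        max_umis = config$qc$max_umis,
        max_mito_fraction = config$qc$max_mito,
        min_cells_per_gene = config$qc$min_cells_per_gene,
        apply_mito_filter = isTRUE(config$qc$mito_filter))
      qc_filter(counts, th)
    })
    counts <- qc$counts
    jsonlite::write_json(qc$report, file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_counts_mtx(counts, file.path(config$out_dir, "filtered_counts"))
    results$qc <- qc$report
  }
  norm <- normalize_log(counts)
  stats_df <- cell_qc_stats(counts)

  # trajectory
  if (isTRUE(config$stages$trajectory)) {
    meta <- stage("trajectory", {
      markers <- if (!is.null(sim)) {
        tg <- sim$truth$gene
        tg$gene_id[tg$is_branch_gene & !is.na(tg$favored) & tg$favored == "U"]
      } else NULL
      tm <- infer_bifurcation(
        norm, n_pcs = config$trajectory$n_pcs,
        n_clusters = config$trajectory$n_clusters,
        marker_genes = markers, seed = config$seed)
      tm <- stretch_pseudotime(tm)
      strata <- stratify_deciles(tm, n_bins = config$trajectory$n_bins)
      tm$decile <- strata$decile[match(tm$cell_id, strata$cell_id)]
      tm
    })
    utils::write.csv(meta, file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    results$trajectory <- meta
  } else {
    stop("the trajectory stage is required by all downstream stages")
  }

  # branch test
  if (isTRUE(config$stages$branchtest)) {
    bt <- stage("branchtest", fit_branch_test(
      norm, meta, spline_df = config$branchtest$spline_df,
      family = config$branchtest$family, counts = counts,
      q_max = config$branchtest$q_max, lfc_min = config$branchtest$lfc_min))
    utils::write.csv(bt, file.path(config$out_dir, "branch_test.csv"),
                     row.names = FALSE)
    results$branchtest <- bt
  }

  # divergence
  if (isTRUE(config$stages$divergence)) {
    div <- stage("divergence", {
      curves <- smooth_branch_curves(
        norm, meta, grid_size = config$divergence$grid,
        bandwidth = config$divergence$bandwidth)
      calls <- detect_divergence(curves, delta = config$divergence$delta,
                                 mode = config$divergence$mode)
      list(curves = curves, calls = calls)
    })
    utils::write.csv(div$calls, file.path(config$out_dir, "divergence.csv"),
                     row.names = FALSE)
    results$divergence <- div$calls
    if (isTRUE(config$stages$branchtest)) {
      sig <- filter_branch_genes(results$branchtest,
                                 q_max = config$branchtest$q_max,
                                 lfc_min = config$branchtest$lfc_min)
      if (length(sig) >= config$branchtest$k) {
        cl <- kinetic_clusters(div$curves, sig, k = config$branchtest$k)
        utils::write.csv(
          data.frame(gene_id = names(cl), kinetic_cluster = as.integer(cl)),
          file.path(config$out_dir, "kinetic_clusters.csv"),
          row.names = FALSE)
        results$kinetic_clusters <- cl
      }
    }
  }

  # deconvolution
  if (isTRUE(config$stages$deconv)) {
    dc <- stage("deconv", {
      sig <- if (!is.null(config$deconv$signature)) {
        read_signature(config$deconv$signature)
      } else {
        # synthetic stand-in signature over the data's own genes
        g <- counts$gene_ids[seq_len(min(100L, length(counts$gene_ids)))]
        s <- synthetic_signature(length(g), seed = config$seed)
        s$gene <- g
        s
      }
      strata <- stratify_deciles(meta, n_bins = config$trajectory$n_bins)
      prof <- build_stratum_profiles(norm, strata)
      estimate_fractions(prof, sig)
    })
    utils::write.csv(dc, file.path(config$out_dir, "deconvolution.csv"),
                     row.names = FALSE)
    results$deconv <- dc
  }

  # enrichment
  if (isTRUE(config$stages$enrich) && isTRUE(config$stages$branchtest)) {
    en <- stage("enrich", {
      terms <- if (!is.null(config$enrich$gmt)) read_gmt(config$enrich$gmt)
      else {
        # default smoke terms: random partitions of the gene universe
        set.seed(config$seed)
        u <- counts$gene_ids
        lapply(stats::setNames(1:5, sprintf("TERM%02d", 1:5)),
               function(i) sample(u, min(50L, length(u) %/% 2L)))
      }
      query <- filter_branch_genes(results$branchtest,
                                   q_max = config$branchtest$q_max,
                                   lfc_min = config$branchtest$lfc_min)
      if (!length(query)) query <- utils::head(
        results$branchtest$gene_id[order(results$branchtest$p)], 10L)
      lfc <- stats::setNames(results$branchtest$avg_logfc,
                             results$branchtest$gene_id)
      hypergeom_enrich(query, terms, universe = counts$gene_ids, logfc = lfc)
    })
    utils::write.csv(en, file.path(config$out_dir, "enrichment.csv"),
                     row.names = FALSE)
    results$enrich <- en
  }

  # manifest
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    package = "adipobranch",
    version = as.character(utils::packageVersion("adipobranch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    files = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Command-line interface
#'
#' Minimal subcommand dispatcher: `simulate`, `qc`, `countdots`, `run-all`.
#' Flags are `--key value` pairs (or bare `--flag` switches). Intended to be
#' called from an Rscript wrapper:
#' `Rscript -e 'adipobranch::adipobranch_cli()' run-all --out-dir run1`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the result of the dispatched command.
#' @export
adipobranch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: adipobranch_cli <simulate|qc|countdots|run-all> [--flags]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  switch(cmd,
    "simulate" = {
      cfg <- sim_config(n_cells = num(opts$`n-cells`, 1000),
                        n_genes = num(opts$`n-genes`, 600),
                        seed = num(opts$seed, 1))
      sim <- simulate_bifurcation(cfg)
      out <- opts$`out-dir` %||% "sim_out"
      write_counts_mtx(sim$counts, out)
      utils::write.csv(sim$meta, file.path(out, "meta.csv"), row.names = FALSE)
      jsonlite::write_json(sim$truth$gene, file.path(out, "truth.json"),
                           digits = NA)
      message("wrote ", out)
      invisible(sim)
    },
    "qc" = {
      cm <- read_counts(opts$input %||% stop("--input required"))
      th <- qc_thresholds(
        min_genes = num(opts$`min-genes`, 200),
        max_genes = num(opts$`max-genes`, 9000),
        max_umis = num(opts$`max-umis`, 120000),
        max_mito_fraction = num(opts$`max-mito`, 0.08),
        apply_mito_filter = is.null(opts$`no-mito-filter`))
      res <- qc_filter(cm, th)
      out <- opts$`out-dir` %||% "qc_out"
      write_counts_mtx(res$counts, out)
      jsonlite::write_json(res$report, file.path(out, "qc_report.json"),
                           auto_unbox = TRUE, digits = NA)
      message("kept ", res$report$cells_kept, " cells / ",
              res$report$genes_kept, " genes")
      invisible(res$report)
    },
    "countdots" = {
      img <- read_pgm(opts$input %||% stop("--input required"))
      res <- count_dots_image(img,
                              n_classes = num(opts$classes, 3),
                              min_size = num(opts$`min-size`, 20),
                              max_size = num(opts$`max-size`, 2000))
      cat(jsonlite::toJSON(res, auto_unbox = TRUE, digits = NA), "\n")
      invisible(res)
    },
    "run-all" = {
      cfg <- if (!is.null(opts$config)) read_config(opts$config)
      else default_config(out_dir = opts$`out-dir` %||% "run_out",
                          seed = num(opts$seed, 1))
      invisible(run_pipeline(cfg))
    },
    stop("unknown subcommand: ", cmd))
}

#' @keywords internal
parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
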