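# Cumulative-hypergeometric gene-set enrichment and the directional
# z-score (up - down) / sqrt(count) used to orient enriched terms between
# the two branches.

#' Cumulative hypergeometric gene-set enrichment
#'
#' For each term, the p-value is the upper tail `P(X >= overlap)` of the
#' hypergeometric distribution over the universe (Fisher's one-tailed
#' test). BH correction is applied across terms. When a per-gene log
#' fold-change vector is supplied, each term also receives `up`/`down`
#' counts over its overlap genes (logFC > 0 counted as upregulated, i.e.
#' higher in the U branch) and the directional z-score
#' `(up - down) / sqrt(up + down)`.
#'
#' @param query character vector of genes of interest; must be contained in
#'   the universe.
#' @param terms named list mapping term id to a character vector of genes;
#'   terms are intersected with the universe.
#' @param universe character vector of background genes (conventionally all
#'   genes surviving QC).
#' @param logfc optional named numeric vector of per-gene log fold changes
#'   (U minus L) used for the z-score.
#' @return data.frame with term, query_size, term_size, universe_size,
#'   overlap, p, q, up, down, z_score.
#' @export
hypergeom_enrich <- function(query, terms, universe, logfc = NULL) {
  query <- unique(query); universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    K <- length(tg)
    ov_genes <- intersect(tg, query)
    ov <- length(ov_genes)
    p <- if (K == 0) 1 else
      stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    up <- down <- NA_integer_; z <- NA_real_
    if (!is.null(logfc) && ov > 0) {
      s <- sign(logfc[ov_genes])
      s <- s[!is.na(s)]
      up <- sum(s > 0); down <- sum(s < 0)
      if (up + down > 0) z <- (up - down) / sqrt(up + down)
    }
    data.frame(term = tm, query_size = n, term_size = K, universe_size = N,
               overlap = ov, p = p, up = up, down = down, z_score = z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("term", "query_size", "term_size", "universe_size", "overlap",
          "p", "q", "up", "down", "z_score")]
}

#' Directional z-score of a term
#'
#' `(up - down) / sqrt(count)` where `up` and `down` are the numbers of
#' genes in the term's overlap with positive and negative log fold change
#' between the branches, and `count = up + down` (genes with zero logFC are
#' excluded). Positive values indicate a term increased in the U branch.
#'
#' @param signs numeric vector of per-gene log fold changes (or their
#'   signs) for the term's overlap genes.
#' @return the z-score.
#' @export
go_zscore <- function(signs) {
  s <- sign(signs)
  up <- sum(s > 0); down <- sum(s < 0)
  count <- up + down
  if (count == 0) stop("z-score undefined: no genes with nonzero log fold change")
  (up - down) / sqrt(count)
}

#' Read a GMT-format term file
#'
#' Tab-separated: term id, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}
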