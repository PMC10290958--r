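#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Implemented in-package (rather
#' than delegating to [stats::p.adjust()]) so that the adjustment used by the
#' branch test and the enrichment module can be verified against a
#' brute-force evaluation of the BH formula
#' \eqn{q_i = \min_{j: p_j \ge p_i} p_j m / \mathrm{rank}(p_j)}.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA` propagates.
#' @return numeric vector of monotone q-values, same length as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(pv[o] * m / seq(m, 1L)))[ro]
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
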