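# Signature-based deconvolution of brown-adipocyte content per branch x
# decile stratum. The published prediction tool's internals are not public;
# this module is a documented stand-in: two-component simplex-constrained
# least squares on unit-sum-normalized marker profiles, validated against
# planted mixtures.

#' Mean non-log expression profiles per stratum
#'
#' For each branch x decile stratum, the per-gene mean of the de-logged
#' normalized expression (`expm1` of the log1p values, i.e. counts scaled to
#' the common transcript total) across member cells.
#'
#' @param norm a `normalized_matrix` with `transform = "log-normalized"`.
#' @param strata a [stratify_deciles()] result.
#' @return strata x genes matrix; rownames are stratum ids.
#' @export
build_stratum_profiles <- function(norm, strata) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (norm$transform != "log-normalized") {
    stop("profiles must be built on log-normalized (not residualized) data")
  }
  s <- strata$stratum[match(rownames(norm$values), strata$cell_id)]
  if (anyNA(s)) stop("strata must cover all cells in the matrix")
  E <- expm1(norm$values)
  grp <- factor(s)
  sums <- rowsum(E, grp)
  n <- as.vector(table(grp)[rownames(sums)])
  sums / n
}

#' Read a brown/white signature matrix
#'
#' @param path CSV with columns `gene`, `brown`, `white`.
#' @return data.frame.
#' @export
read_signature <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "brown", "white") %in% names(df))) {
    stop("signature file must have columns gene, brown, white")
  }
  if (anyDuplicated(df$gene)) stop("duplicate genes in signature")
  if (any(df$brown < 0) || any(df$white < 0)) stop("signature values must be >= 0")
  df
}

#' Estimate brown fractions by constrained least squares
#'
#' Restricts each profile to the signature genes, scales profile and
#' signature columns to unit sum, and solves
#' `min || p - (f * brown + (1 - f) * white) ||^2` over `f` in \[0, 1\] in
#' closed form (projection onto the segment between the two signature
#' columns, clipped to the simplex).
#'
#' @param profiles strata x genes matrix (e.g. [build_stratum_profiles()])
#'   or a genes x mixtures matrix from [simulate_mixture()] (auto-detected
#'   by gene orientation).
#' @param signature data.frame with `gene`, `brown`, `white`.
#' @return data.frame with stratum, brown_fraction, residual.
#' @export
estimate_fractions <- function(profiles, signature) {
  stopifnot(all(c("gene", "brown", "white") %in% names(signature)))
  if (is.null(colnames(profiles)) || is.null(rownames(profiles))) {
    stop("profiles must carry dimnames")
  }
  # orient strata x genes
  if (!any(signature$gene %in% colnames(profiles)) &&
      any(signature$gene %in% rownames(profiles))) {
    profiles <- t(profiles)
  }
  common <- intersect(signature$gene, colnames(profiles))
  if (length(common) < 2) stop("fewer than 2 signature genes present in data")
  si <- match(common, signature$gene)
  b_raw <- signature$brown[si]; w_raw <- signature$white[si]
  Sb <- sum(b_raw); Sw <- sum(w_raw)
  if (Sb <= 0 || Sw <= 0) stop("degenerate signature column")
  b <- b_raw / Sb; w <- w_raw / Sw
  if (isTRUE(all.equal(b, w))) {
    stop("signature columns are identical: fractions are unidentifiable")
  }
  P <- profiles[, common, drop = FALSE]
  out <- t(apply(P, 1, function(p) {
    tot <- sum(p)
    if (tot <= 0) return(c(NA_real_, NA_real_))
    p <- p / tot
    dbw <- b - w
    fp <- sum((p - w) * dbw) / sum(dbw^2)
    fp <- min(max(fp, 0), 1)
    r <- sqrt(sum((p - (fp * b + (1 - fp) * w))^2))
    # fp is the fraction on the unit-sum scale; convert back to the raw
    # mixing fraction (mRNA-content correction: the two signature columns
    # need not have equal totals)
    f <- fp * Sw / (Sb * (1 - fp) + fp * Sw)
    c(f, r)
  }))
  data.frame(stratum = rownames(P), brown_fraction = out[, 1],
             residual = out[, 2], stringsAsFactors = FALSE, row.names = NULL)
}
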