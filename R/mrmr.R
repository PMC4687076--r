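# Minimal-redundancy-maximal-relevance (mRMR) feature ranking on
# discrete genotype data, using plug-in mutual information.
#
# Relevance of SNP f is D = I(f, c), its mutual information with the
# population label c; redundancy with an already-selected set S of m
# SNPs is R = (1/m) * sum_{f_i in S} I(f, f_i).  The greedy MID
# (difference) scheme repeatedly selects the candidate maximising
# D - R; the first pick maximises relevance alone.  Genotypes (3
# states) and labels are already categorical, so the maximum-likelihood
# plug-in estimate is used directly, without binning or bias
# correction.

# fast plug-in MI for integer codes x in 1..nx, y in 1..ny, no NAs
mi_codes <- function(x, y, nx, ny, base = 2) {
  n <- length(x)
  joint <- tabulate((y - 1L) * nx + x, nbins = nx * ny)
  px <- tabulate(x, nbins = nx) / n
  py <- tabulate(y, nbins = ny) / n
  nz <- which(joint > 0L)
  pj <- joint[nz] / n
  ix <- (nz - 1L) %% nx + 1L
  iy <- (nz - 1L) %/% nx + 1L
  sum(pj * log(pj / (px[ix] * py[iy]))) / log(base)
}

#' Mutual information between two discrete vectors
#'
#' Maximum-likelihood ("plug-in") estimate
#' `I = sum p(a,b) * log2( p(a,b) / (p(a) p(b)) )` over observed cells,
#' in bits by default.  Non-negative and symmetric in its arguments;
#' `I(X, X)` equals the entropy of `X`.  Pairs in which either value is
#' `NA` are excluded.
#'
#' @param x,y vectors of equal length; any discrete type (integer,
#'   character, factor).
#' @param base logarithm base; 2 (bits) by default.
#' @return the estimated mutual information.
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  keep <- !(is.na(x) | is.na(y))
  if (!any(keep)) stop("no complete (x, y) pairs to estimate from")
  xf <- factor(x[keep])
  yf <- factor(y[keep])
  mi_codes(as.integer(xf), as.integer(yf), nlevels(xf), nlevels(yf), base)
}

#' Rank candidate SNPs by mRMR
#'
#' Greedy MID-scheme ranking: the first SNP maximises relevance
#' `I(f, c)`; each subsequent step selects the remaining candidate
#' maximising relevance minus mean mutual information with the SNPs
#' already selected.  Run for `n_select` rounds (all candidates by
#' default, giving a full ranked list).  Pairwise MI terms are computed
#' lazily -- each newly selected SNP against the remaining candidates --
#' and accumulated, so no all-pairs MI matrix is formed.  Ties in the
#' selection score are broken toward the lowest original column index.
#' The selected order is invariant to the logarithm base; reported
#' values use `base`.
#'
#' @param x complete integer matrix (samples x candidate SNPs), coded
#'   0/1/2; impute missing calls first (see [impute_modal()]).
#' @param labels per-sample population labels (the class variable).
#' @param n_select number of ranking rounds; defaults to all candidates.
#' @param base logarithm base for reported relevance/redundancy values.
#' @return an object of class `mrmr_ranking`: a data frame with columns
#'   `rank`, `index` (original column index), `rsid`, `relevance`
#'   (D at selection), `redundancy` (R at selection; 0 for the first
#'   pick) and `score` (D - R), ordered by rank.
#' @export
mrmr_rank <- function(x, labels, n_select = ncol(x), base = 2) {
  stopifnot(is.matrix(x))
  m <- ncol(x)
  if (m < 1L) stop("at least one candidate SNP is required")
  if (nrow(x) != length(labels)) stop("labels must match matrix rows")
  if (n_select > m) stop("n_select exceeds the number of candidates")
  if (anyNA(x)) stop("candidate matrix contains missing values; impute first")

  y <- as_population_factor(labels)
  yi <- as.integer(y); ny <- nlevels(y)
  xi <- x + 1L  # genotype codes 1..3
  storage.mode(xi) <- "integer"

  relevance <- vapply(seq_len(m), function(j) {
    mi_codes(xi[, j], yi, 3L, ny, base)
  }, numeric(1))

  order_idx <- integer(n_select)
  rel_sel <- red_sel <- score_sel <- numeric(n_select)
  remaining <- rep(TRUE, m)
  red_sum <- numeric(m)  # cumulative sum of MI with selected SNPs

  for (h in seq_len(n_select)) {
    m_sel <- h - 1L
    score <- relevance - if (m_sel > 0L) red_sum / m_sel else 0
    score[!remaining] <- -Inf
    pick <- which.max(score)  # which.max returns the first (lowest index) tie
    order_idx[h] <- pick
    rel_sel[h] <- relevance[pick]
    red_sel[h] <- if (m_sel > 0L) red_sum[pick] / m_sel else 0
    score_sel[h] <- score[pick]
    remaining[pick] <- FALSE
    if (h < n_select) {
      idx <- which(remaining)
      for (j in idx) {
        red_sum[j] <- red_sum[j] + mi_codes(xi[, j], xi[, pick], 3L, 3L, base)
      }
    }
  }

  rsids <- colnames(x) %||% as.character(seq_len(m))
  structure(
    data.frame(
      rank = seq_len(n_select), index = order_idx, rsid = rsids[order_idx],
      relevance = rel_sel, redundancy = red_sel, score = score_sel,
      stringsAsFactors = FALSE
    ),
    class = c("mrmr_ranking", "data.frame")
  )
}
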