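# Internal helpers shared across modules.

#' Round to the nearest integer, ties to even
#'
#' Banker's rounding with an explicit tolerance for the half-way case, so
#' that values such as `110 * 0.15` (16.5 up to floating-point error) are
#' treated as exact ties rather than left to binary representation.
#'
#' @param x numeric vector.
#' @param tol half-way detection tolerance.
#' @return integer vector.
#' @keywords internal
round_half_even <- function(x, tol = 1e-9) {
  lo <- floor(x)
  frac <- x - lo
  out <- ifelse(frac > 0.5, lo + 1, lo)
  tie <- abs(frac - 0.5) < tol
  # on a tie pick the even neighbour
  out[tie] <- ifelse(lo[tie] %% 2 == 0, lo[tie], lo[tie] + 1)
  as.integer(out)
}

#' Impute missing genotype calls to the per-SNP modal status
#'
#' Replaces every missing call with the most frequent status of that SNP
#' among a designated set of (training) samples.  Downstream consumers
#' that require complete data -- mutual-information ranking and all
#' classifiers -- are fed through this function; the association filter
#' instead excludes missing calls per SNP and never sees imputed values.
#'
#' @param values integer matrix of genotypes in `{0, 1, 2, NA}`
#'   (samples x SNPs).
#' @param train integer vector of row indices from which modal statuses
#'   are computed (defaults to all rows).  Using the training rows only
#'   avoids leaking test-set information into the imputation.
#' @return the matrix with every `NA` replaced; a column whose training
#'   slice is entirely missing is imputed to 0 with a warning.
#' @export
impute_modal <- function(values, train = seq_len(nrow(values))) {
  stopifnot(is.matrix(values))
  if (!anyNA(values)) return(values)
  all_missing <- character(0)
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    if (!anyNA(col)) next
    tr <- col[train]
    counts <- tabulate(tr + 1L, nbins = 3L)
    if (sum(counts) == 0L) {
      mode_val <- 0L
      all_missing <- c(all_missing, colnames(values)[j] %||% as.character(j))
    } else {
      # ties resolved toward the smallest status
      mode_val <- which.max(counts) - 1L
    }
    col[is.na(col)] <- mode_val
    values[, j] <- col
  }
  if (length(all_missing) > 0) {
    warning(sprintf(
      "%d SNP(s) with no observed training calls imputed to 0 (e.g. %s)",
      length(all_missing), all_missing[1]
    ))
  }
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Labels are handled internally as factors whose level order is sorted;
# lexicographic tie-breaking rules in the classifiers rely on this.
as_population_factor <- function(labels) {
  if (is.factor(labels)) factor(labels, levels = sort(levels(labels)))
  else factor(labels, levels = sort(unique(as.character(labels))))
}
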