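# Per-SNP association between genotype status and population labels,
# measured by Cramer's V, and the candidate-SNP filter.
#
# For a k-population x r-status table of observed counts O_ij with row
# totals n_i, column totals m_j and total N, Pearson's statistic is
#   chi^2 = sum_ij (O_ij - E_ij)^2 / E_ij,  E_ij = n_i * m_j / N,
# and Cramer's V = sqrt( (chi^2 / N) / min(k - 1, r - 1) ), a [0, 1]
# effect size: 0 means no association between SNP status and
# population, 1 a complete association.

#' Build a population x genotype-status contingency table for one SNP
#'
#' Missing calls are excluded; populations present in the labels form
#' the rows and genotype statuses observed among non-missing calls form
#' the columns, so empty status columns are dropped (`r_eff` counts the
#' statuses that remain; for a common SNP with all three statuses
#' present `r_eff` is 3).
#'
#' @param genotypes integer vector of coded genotypes in
#'   `{0, 1, 2, NA}` for one SNP.
#' @param labels population labels, same length.
#' @return an object of class `contingency_table` with fields `O`
#'   (counts), `k_eff`, `r_eff`, `N`, `row_totals`, `col_totals` and
#'   `degenerate` (`TRUE` when no non-missing call remains, in which
#'   case V is defined as 0).
#' @export
contingency_table <- function(genotypes, labels) {
  if (length(genotypes) != length(labels)) {
    stop("genotypes and labels must have the same length")
  }
  keep <- !is.na(genotypes)
  if (!any(keep)) {
    out <- list(O = matrix(0L, 0L, 0L), k_eff = 0L, r_eff = 0L, N = 0L,
                row_totals = integer(0), col_totals = integer(0),
                degenerate = TRUE)
    return(structure(out, class = "contingency_table"))
  }
  O <- table(factor(labels[keep]), factor(genotypes[keep]))
  O <- unclass(O)[rowSums(O) > 0, , drop = FALSE]
  storage.mode(O) <- "integer"
  structure(
    list(
      O = O, k_eff = nrow(O), r_eff = ncol(O), N = sum(O),
      row_totals = rowSums(O), col_totals = colSums(O),
      degenerate = FALSE
    ),
    class = "contingency_table"
  )
}

as_contingency <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.matrix(x)) {
    O <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
    return(structure(
      list(O = O, k_eff = nrow(O), r_eff = ncol(O), N = sum(O),
           row_totals = rowSums(O), col_totals = colSums(O),
           degenerate = sum(O) == 0),
      class = "contingency_table"
    ))
  }
  stop("expected a contingency_table or a count matrix")
}

#' Pearson's chi-squared statistic of a contingency table
#'
#' @param x a `contingency_table` from [contingency_table()] or a plain
#'   count matrix (empty rows/columns are dropped first).
#' @return the statistic; zero exactly when observed counts equal their
#'   expectations everywhere.
#' @export
chi_squared_stat <- function(x) {
  tab <- as_contingency(x)
  if (tab$degenerate || tab$N == 0L) return(0)
  E <- outer(tab$row_totals, tab$col_totals) / tab$N
  sum((tab$O - E)^2 / E)
}

#' Cramer's V association coefficient
#'
#' `V = sqrt((chi^2 / N) / min(k_eff - 1, r_eff - 1))`, in `[0, 1]`.  A
#' SNP monomorphic among non-missing calls (`r_eff = 1`) carries no
#' association information and gets V = 0 by definition, as does a
#' degenerate (all-missing) table.
#'
#' @inheritParams chi_squared_stat
#' @return V in `[0, 1]`.
#' @export
cramers_v <- function(x) {
  tab <- as_contingency(x)
  if (tab$degenerate || tab$r_eff < 2L || tab$k_eff < 2L) return(0)
  chi2 <- chi_squared_stat(tab)
  v <- sqrt((chi2 / tab$N) / min(tab$k_eff - 1L, tab$r_eff - 1L))
  min(v, 1)  # clip numerical overshoot at the upper bound
}

# single streaming pass over one SNP column: counts via tabulate,
# avoiding table() overhead in the genome-wide scan
cramers_v_one <- function(genotypes, label_codes, k) {
  keep <- !is.na(genotypes)
  n_used <- sum(keep)
  if (n_used == 0L) {
    return(c(chi2 = 0, v = 0, k_eff = 0, r_eff = 0, n_used = 0))
  }
  g <- genotypes[keep]
  y <- label_codes[keep]
  O <- matrix(tabulate(y + k * g, nbins = 3L * k), k, 3L)
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  k_eff <- nrow(O); r_eff <- ncol(O)
  if (r_eff < 2L || k_eff < 2L) {
    return(c(chi2 = 0, v = 0, k_eff = k_eff, r_eff = r_eff, n_used = n_used))
  }
  N <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / N
  chi2 <- sum((O - E)^2 / E)
  v <- min(sqrt((chi2 / N) / min(k_eff - 1L, r_eff - 1L)), 1)
  c(chi2 = chi2, v = v, k_eff = k_eff, r_eff = r_eff, n_used = n_used)
}

#' Filter SNPs by Cramer's V association with population labels
#'
#' Computes V for every SNP and keeps those with V strictly greater
#' than the threshold (SNPs with V less than or equal to the threshold
#' are removed), preserving original genomic order.  Intended to run on
#' the training samples only; the function filters whatever matrix it
#' is given.
#'
#' @param x a [genotype_matrix()] or a plain integer matrix
#'   (samples x SNPs) of coded genotypes.
#' @param labels per-sample population labels.
#' @param threshold association cut-off; default 0.6.
#' @return a list with `candidates` (integer column indices of passing
#'   SNPs, original order) and `results`, a data frame with one row per
#'   SNP: `rsid`, `chi_squared`, `cramers_v`, `k_eff`, `r_eff`,
#'   `n_used`, `pass`.  If no SNP passes, `candidates` is empty and a
#'   warning is raised.
#' @export
filter_snps <- function(x, labels, threshold = 0.6) {
  values <- if (inherits(x, "genotype_matrix")) x$values else x
  stopifnot(is.matrix(values))
  if (nrow(values) != length(labels)) {
    stop("labels must match matrix rows")
  }
  y <- as_population_factor(labels)
  codes <- as.integer(y)
  k <- nlevels(y)
  m <- ncol(values)
  stats_mat <- matrix(0, m, 5L)
  for (j in seq_len(m)) {
    stats_mat[j, ] <- cramers_v_one(values[, j], codes, k)
  }
  rsids <- colnames(values) %||% as.character(seq_len(m))
  results <- data.frame(
    rsid = rsids,
    chi_squared = stats_mat[, 1],
    cramers_v = stats_mat[, 2],
    k_eff = as.integer(stats_mat[, 3]),
    r_eff = as.integer(stats_mat[, 4]),
    n_used = as.integer(stats_mat[, 5]),
    pass = stats_mat[, 2] > threshold,
    stringsAsFactors = FALSE
  )
  candidates <- which(results$pass)
  if (length(candidates) == 0L) {
    warning(sprintf("no SNP exceeds Cramer's V threshold %.3f", threshold))
  }
  list(candidates = candidates, results = results, threshold = threshold)
}
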