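# Train/test splitting, accuracy bookkeeping, repeated-split summaries
# and per-group minor-allele-frequency reports.
#
# Accuracy is reported per group as Q_i = T_i / N_i (T_i correct
# predictions among the N_i samples of group i) and in total as
# Q = sum(T_i) / sum(N_i), the sample-weighted mean of the Q_i.

#' Specify a stratified train/test split
#'
#' @param test_fraction fraction of each group allocated to the test
#'   set, in (0, 1); default 0.15.  Per-group allocations are rounded to
#'   the nearest integer with ties to even (so a group of 110 at 15%
#'   contributes 16 test samples, and one of 87 contributes 13).
#' @param seed RNG seed for the within-group sampling.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.15, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie in (0, 1)")
  }
  structure(list(test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Allocates `round_half_even(test_fraction * n_g)` samples of each
#' group g to the test set, sampled uniformly without replacement under
#' the seed; the remainder form the training set.  Deterministic given
#' the seed.
#'
#' @param labels per-sample group labels.
#' @param spec a [split_spec()].
#' @return list with sorted integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  y <- as_population_factor(labels)
  set.seed(spec$seed)
  test <- integer(0)
  for (g in levels(y)) {
    idx <- which(y == g)
    n_g <- length(idx)
    n_test <- round_half_even(spec$test_fraction * n_g)
    if (n_test >= n_g) {
      stop(sprintf("group %s would have no training samples", g))
    }
    if (n_test > 0L) test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# stratified fold assignment: per class, a shuffled balanced 1..k cycle
make_stratified_folds <- function(labels, n_folds, seed) {
  y <- as_population_factor(labels)
  sizes <- table(y)
  if (any(sizes < n_folds)) {
    small <- names(sizes)[which.min(sizes)]
    stop(sprintf(
      "class %s has %d samples, fewer than %d folds; use fewer folds",
      small, min(sizes), n_folds
    ))
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (g in levels(y)) {
    idx <- which(y == g)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Build an evaluation report from actual and predicted labels
#'
#' @param actual,predicted label vectors of equal length.
#' @return an object of class `evaluation_report`: `confusion`
#'   (actual x predicted counts over the union of label sets),
#'   `per_group_accuracy` (Q_i), `total_accuracy` (Q), `N_i`, `T_i`.
#' @export
evaluation_report <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  lev <- sort(unique(c(as.character(actual), as.character(predicted))))
  a <- factor(as.character(actual), levels = lev)
  p <- factor(as.character(predicted), levels = lev)
  confusion <- unclass(table(actual = a, predicted = p))
  groups <- lev[rowSums(confusion) > 0]
  N_i <- rowSums(confusion)[groups]
  T_i <- diag(confusion)[groups]
  structure(
    list(
      confusion = confusion,
      per_group_accuracy = T_i / N_i,
      total_accuracy = sum(T_i) / sum(N_i),
      N_i = N_i, T_i = T_i
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("total accuracy Q = %.4f over %d samples\n",
              x$total_accuracy, sum(x$N_i)))
  print(round(x$per_group_accuracy, 4))
  invisible(x)
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Folds are stratified by class and fixed by the seed; every sample is
#' predicted exactly once by the model trained on the other folds, and
#' predictions are pooled into a single report.
#'
#' @param x complete feature matrix.
#' @param labels class labels; every class needs at least `n_folds`
#'   members.
#' @param spec a [predictor_spec()].
#' @param n_folds number of folds; default 10.
#' @param seed fold-assignment seed.
#' @return an [evaluation_report()] with attribute `fold` (the
#'   assignment vector).
#' @export
cross_validate <- function(x, labels, spec, n_folds = 10L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  fold <- make_stratified_folds(labels, n_folds, seed)
  pred <- character(length(labels))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    model <- fit_predictor(spec, x[tr, , drop = FALSE], labels[tr])
    pred[!tr] <- predict(model, x[!tr, , drop = FALSE])
  }
  rep <- evaluation_report(labels, pred)
  attr(rep, "fold") <- fold
  rep
}

#' Train on one index set, evaluate on a disjoint one
#'
#' @param x complete feature matrix covering all samples.
#' @param labels labels for all samples.
#' @param train,test disjoint integer index vectors.
#' @param spec a [predictor_spec()].
#' @return an [evaluation_report()] on the test samples.
#' @export
evaluate_split <- function(x, labels, train, test, spec) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (length(intersect(train, test)) > 0L) {
    stop("train and test indices overlap")
  }
  model <- fit_predictor(spec, x[train, , drop = FALSE], labels[train])
  pred <- predict(model, x[test, , drop = FALSE])
  evaluation_report(labels[test], pred)
}

#' Repeat the full selection pipeline over independent splits
#'
#' Each repetition draws a fresh stratified train/test split (seeds
#' `spec$seed, spec$seed + 1, ...`), re-runs the pipeline on the
#' training slice -- modal imputation, Cramer's V filter, mRMR ranking,
#' then either a fixed-size top prefix or IFS plateau selection -- and
#' records the training cross-validation accuracy and the independent
#' test accuracy of the selected panel.
#'
#' @param gm a [genotype_matrix()] or plain coded matrix.
#' @param labels per-sample population labels.
#' @param spec a [split_spec()]; its seed anchors the repetition seeds.
#' @param n_reps number of repetitions; default 30.
#' @param threshold Cramer's V cut-off; default 0.6.
#' @param classifier a [predictor_spec()]; default smo.
#' @param n_snps fixed panel size (top-`n_snps` of the ranking).  If
#'   `NULL`, IFS plateau selection with (`ifs_max_i`, `ifs_step`,
#'   `theta`, `delta`) picks the size per repetition.
#' @param ifs_max_i,ifs_step,theta,delta IFS settings when `n_snps` is
#'   `NULL`.
#' @param n_folds cross-validation folds; default 10.
#' @return an object of class `repetition_summary`: per-repetition data
#'   frame (`rep`, `seed`, `n_candidates`, `n_snps_used`, `cv_accuracy`,
#'   `test_accuracy`) plus `mean_cv`, `sd_cv`, `mean_test`, `sd_test`
#'   (standard deviations defined as 0 for a single repetition).
#' @export
repeat_splits <- function(gm, labels, spec = split_spec(), n_reps = 30L,
                          threshold = 0.6,
                          classifier = predictor_spec("smo"),
                          n_snps = NULL, ifs_max_i = 60L, ifs_step = 5L,
                          theta = 0.90, delta = 0.01, n_folds = 10L) {
  values <- if (inherits(gm, "genotype_matrix")) gm$values else gm
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    seed_r <- spec$seed + r - 1L
    res <- tryCatch(
      run_aims_pipeline(
        values, labels, split = split_spec(spec$test_fraction, seed_r),
        threshold = threshold, classifier = classifier,
        n_snps = n_snps, ifs_max_i = ifs_max_i, ifs_step = ifs_step,
        theta = theta, delta = delta, n_folds = n_folds, seed = seed_r
      ),
      error = function(e) stop(sprintf("repetition %d failed: %s",
                                       r, conditionMessage(e)))
    )
    rows[[r]] <- data.frame(
      rep = r, seed = seed_r,
      n_candidates = length(res$filter$candidates),
      n_snps_used = res$n_snps_used,
      cv_accuracy = res$cv_report$total_accuracy,
      test_accuracy = res$test_report$total_accuracy
    )
  }
  tab <- do.call(rbind, rows)
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  structure(
    list(
      repetitions = tab,
      mean_cv = mean(tab$cv_accuracy), sd_cv = sd0(tab$cv_accuracy),
      mean_test = mean(tab$test_accuracy), sd_test = sd0(tab$test_accuracy)
    ),
    class = "repetition_summary"
  )
}

#' @export
print.repetition_summary <- function(x, ...) {
  cat(sprintf(
    "%d repetitions: CV accuracy %.4f (sd %.4f), test accuracy %.4f (sd %.4f)\n",
    nrow(x$repetitions), x$mean_cv, x$sd_cv, x$mean_test, x$sd_test
  ))
  invisible(x)
}

#' Per-group minor-allele frequency
#'
#' For each group and SNP, the frequency of the counted (minor) allele:
#' the sum of coded genotypes over 2 x the number of non-missing calls
#' in the group.
#'
#' @param gm a [genotype_matrix()] or plain coded matrix.
#' @param labels per-sample group labels.
#' @return numeric matrix (groups x SNPs) in `[0, 1]`; `NA` where a
#'   group has no non-missing call at a SNP.
#' @export
minor_allele_frequency <- function(gm, labels) {
  values <- if (inherits(gm, "genotype_matrix")) gm$values else gm
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  y <- as_population_factor(labels)
  out <- matrix(NA_real_, nlevels(y), ncol(values),
                dimnames = list(levels(y), colnames(values)))
  for (g in levels(y)) {
    sub <- values[y == g, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    freq <- colSums(sub, na.rm = TRUE) / (2 * n_obs)
    freq[n_obs == 0L] <- NA_real_
    out[g, ] <- freq
  }
  out
}
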