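# Incremental feature selection (IFS): score nested top-i prefixes of a
# ranked SNP list by cross-validated accuracy and pick the optimal
# panel size, either at the accuracy maximum or at the first plateau
# point.

#' Build an IFS curve over nested top-i SNP prefixes
#'
#' For each evaluated prefix size i, runs stratified `n_folds`-fold
#' cross-validation of the classifier on the top-i ranked SNPs and
#' records the total and per-group accuracies.  The fold assignment is
#' built once from the seed and shared across all prefix sizes, so the
#' points of the curve are paired comparisons.
#'
#' @param ranking an `mrmr_ranking` from [mrmr_rank()], or a plain
#'   integer vector of column indices in rank order.
#' @param x complete feature matrix covering all ranked columns.
#' @param labels class labels.
#' @param spec a [predictor_spec()].
#' @param max_i largest prefix size; defaults to the full ranking.
#' @param step stride between evaluated sizes: i = step, 2*step, ...
#'   up to `max_i`; default 1 (every prefix).
#' @param n_folds,seed cross-validation settings.
#' @return an object of class `ifs_curve`: a data frame with columns
#'   `i`, `q_total` and one `q_<group>` column per group, with
#'   attributes `fold` (shared fold assignment), `order` (ranked column
#'   indices) and `classifier`.
#' @export
run_ifs <- function(ranking, x, labels, spec, max_i = NULL, step = 1L,
                    n_folds = 10L, seed = 1L) {
  order_idx <- if (inherits(ranking, "mrmr_ranking")) ranking$index
               else as.integer(ranking)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (anyDuplicated(order_idx)) stop("ranking contains duplicate columns")
  if (is.null(max_i)) max_i <- length(order_idx)
  if (max_i > length(order_idx)) stop("max_i exceeds the ranking length")
  sizes <- seq(step, max_i, by = step)
  if (length(sizes) == 0L) stop("no prefix sizes to evaluate")

  fold <- make_stratified_folds(labels, n_folds, seed)
  y <- as_population_factor(labels)
  groups <- levels(y)

  rows <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    i <- sizes[s]
    cols <- order_idx[seq_len(i)]
    pred <- character(length(labels))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      model <- fit_predictor(spec, x[tr, cols, drop = FALSE], labels[tr])
      pred[!tr] <- predict(model, x[!tr, cols, drop = FALSE])
    }
    rep <- evaluation_report(labels, pred)
    qg <- rep$per_group_accuracy[groups]
    row <- data.frame(i = i, q_total = rep$total_accuracy)
    row[paste0("q_", groups)] <- as.list(qg)
    rows[[s]] <- row
  }
  curve <- do.call(rbind, rows)
  attr(curve, "fold") <- fold
  attr(curve, "order") <- order_idx
  attr(curve, "classifier") <- spec$name
  class(curve) <- c("ifs_curve", "data.frame")
  curve
}

#' Choose the optimal prefix size from an IFS curve
#'
#' Mode `"max"` returns the smallest evaluated i achieving the maximum
#' total accuracy.  Mode `"plateau"` codifies the usual visual rule
#' ("the curve becomes stable and stays above the target") as: the
#' smallest evaluated i with total accuracy at least `theta` such that
#' no later evaluated point exceeds it by more than `delta`.
#'
#' @param curve an `ifs_curve` from [run_ifs()].
#' @param mode `"max"` or `"plateau"`.
#' @param theta plateau accuracy floor; default 0.90.
#' @param delta allowed later improvement; default 0.01.  `delta = Inf`
#'   reduces the rule to "first i with accuracy >= theta".
#' @return a list: `found` (logical; `FALSE` only when no plateau
#'   qualifies), `i` (chosen prefix size or `NA`), `accuracy`,
#'   `indices` (the chosen ranked column indices) and `mode`.
#' @export
select_optimal <- function(curve, mode = c("max", "plateau"),
                           theta = 0.90, delta = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "ifs_curve"), nrow(curve) > 0)
  q <- curve$q_total
  order_idx <- attr(curve, "order")
  pick <- NA_integer_
  if (mode == "max") {
    pick <- which(q == max(q))[1]
  } else {
    # running maximum of accuracies strictly after each point
    later_max <- rev(cummax(rev(c(q[-1], -Inf))))
    ok <- q >= theta & later_max <= q + delta
    if (any(ok)) pick <- which(ok)[1]
  }
  if (is.na(pick)) {
    return(list(found = FALSE, i = NA_integer_, accuracy = NA_real_,
                indices = integer(0), mode = mode))
  }
  i <- curve$i[pick]
  list(found = TRUE, i = i, accuracy = q[pick],
       indices = order_idx[seq_len(i)], mode = mode)
}
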