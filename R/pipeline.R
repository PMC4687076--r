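# End-to-end wiring: stratified split -> modal imputation (training
# statistics) -> Cramer's V filter on the training slice -> mRMR
# ranking -> IFS or fixed-size panel -> training cross-validation and
# independent-test evaluation.

#' Run the full ancestry-informative SNP selection pipeline
#'
#' Splits the samples into stratified training/test sets, screens SNPs
#' by Cramer's V association with the population labels on the training
#' slice (missing calls excluded per SNP), imputes missing calls to the
#' training modal status, ranks the candidates by mRMR, selects a panel
#' (a fixed top-`n_snps` prefix, or the IFS plateau when `n_snps` is
#' `NULL`), and reports training cross-validation and independent-test
#' accuracy for the selected panel.
#'
#' @param gm a [genotype_matrix()] or plain coded matrix
#'   (samples x SNPs).
#' @param labels per-sample population labels.
#' @param split a [split_spec()].
#' @param threshold Cramer's V cut-off; default 0.6.
#' @param classifier a [predictor_spec()]; default one-vs-one linear
#'   SVM.
#' @param n_rank number of mRMR rounds; defaults to what the panel
#'   selection needs (`ifs_max_i`, or `n_snps`), capped at the number
#'   of candidates.
#' @param n_snps fixed panel size, or `NULL` for IFS plateau selection.
#' @param ifs_max_i,ifs_step largest prefix and stride of the IFS
#'   curve.
#' @param select_mode,theta,delta IFS selection rule (see
#'   [select_optimal()]); if no plateau qualifies, the accuracy maximum
#'   over the evaluated curve is used as a fallback and flagged in the
#'   result.
#' @param n_folds cross-validation folds; default 10.
#' @param seed seed for fold assignment (and any randomized
#'   classifier).
#' @return a list: `split`, `filter` (per-SNP association results),
#'   `ranking`, `curve` (`NULL` for fixed panels), `selection`,
#'   `n_snps_used`, `panel` (selected rsids), `cv_report`,
#'   `test_report`.
#' @export
run_aims_pipeline <- function(gm, labels, split = split_spec(),
                              threshold = 0.6,
                              classifier = predictor_spec("smo"),
                              n_rank = NULL, n_snps = NULL,
                              ifs_max_i = 60L, ifs_step = 5L,
                              select_mode = "plateau",
                              theta = 0.90, delta = 0.01,
                              n_folds = 10L, seed = 1L) {
  values <- if (inherits(gm, "genotype_matrix")) gm$values else gm
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  labels <- as.character(labels)

  idx <- stratified_split(labels, split)
  train <- idx$train; test <- idx$test
  y_train <- labels[train]

  # association filter on raw training calls (missing excluded per SNP)
  filt <- filter_snps(values[train, , drop = FALSE], y_train, threshold)
  cand <- filt$candidates
  if (length(cand) == 0L) stop("no candidate SNPs pass the association filter")

  # complete data for ranking and classification; training statistics only
  imputed <- impute_modal(values, train = train)

  need <- if (is.null(n_snps)) ifs_max_i else n_snps
  if (is.null(n_rank)) n_rank <- need
  n_rank <- min(n_rank, length(cand))
  if (need > n_rank && is.null(n_snps)) ifs_max_i <- n_rank
  if (!is.null(n_snps) && n_snps > n_rank) {
    stop("n_snps exceeds the number of ranked candidates")
  }
  ranking <- mrmr_rank(imputed[train, cand, drop = FALSE], y_train,
                       n_select = n_rank)
  ranked_cols <- cand[ranking$index]  # back to original column indices

  curve <- NULL
  selection <- NULL
  if (is.null(n_snps)) {
    curve <- run_ifs(ranked_cols, imputed[train, , drop = FALSE], y_train,
                     classifier, max_i = min(ifs_max_i, length(ranked_cols)),
                     step = ifs_step, n_folds = n_folds, seed = seed)
    selection <- select_optimal(curve, mode = select_mode,
                                theta = theta, delta = delta)
    if (!selection$found) {
      selection <- select_optimal(curve, mode = "max")
      selection$fallback <- TRUE
    }
    n_used <- selection$i
    panel_cols <- selection$indices
  } else {
    n_used <- n_snps
    panel_cols <- ranked_cols[seq_len(n_snps)]
  }

  cv_report <- cross_validate(imputed[train, panel_cols, drop = FALSE],
                              y_train, classifier, n_folds = n_folds,
                              seed = seed)
  test_report <- evaluate_split(imputed[, panel_cols, drop = FALSE], labels,
                                train, test, classifier)

  rsids <- colnames(values) %||% as.character(seq_len(ncol(values)))
  list(
    split = idx, filter = filt, ranking = ranking, curve = curve,
    selection = selection, n_snps_used = n_used,
    panel = rsids[panel_cols], panel_columns = panel_cols,
    cv_report = cv_report, test_report = test_report
  )
}
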