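# The four multi-class classifiers compared by the pipeline:
#   smo           one-vs-one soft-margin linear SVM with majority voting
#                 (the classical "SMO" configuration; any convergent SVM
#                 optimizer satisfies the contract, here libsvm via
#                 e1071), features standardized internally
#   ib1           1-nearest-neighbour with per-feature min-max
#                 normalization
#   dagging       disjoint-subset voting ensemble over a base learner
#                 (default: the smo configuration)
#   random_forest bagged decision trees, floor(sqrt(M)) features per
#                 split (randomForest)
# Vote ties are broken toward the lexicographically smallest label;
# ib1 distance ties toward the earliest training index.

#' Specify a classifier
#'
#' @param name one of `"smo"`, `"ib1"`, `"dagging"`, `"random_forest"`.
#' @param C soft-margin cost of the linear SVM (smo and the dagging base
#'   learner); default 1.
#' @param k_subsets number of disjoint training subsets for dagging;
#'   default 10.
#' @param n_trees number of trees for the random forest; default 100.
#' @param seed seed for the randomized learners (dagging's partition,
#'   the forest's bootstraps); smo and ib1 are fully deterministic.
#' @return an object of class `predictor_spec`.
#' @export
predictor_spec <- function(name = c("smo", "ib1", "dagging", "random_forest"),
                           C = 1, k_subsets = 10L, n_trees = 100L,
                           seed = 1L) {
  name <- match.arg(name)
  stopifnot(C > 0, k_subsets >= 1, n_trees >= 1)
  structure(
    list(name = name, C = C, k_subsets = as.integer(k_subsets),
         n_trees = as.integer(n_trees), seed = as.integer(seed)),
    class = "predictor_spec"
  )
}

#' Fit a classifier to a training set
#'
#' @param spec a [predictor_spec()].
#' @param x complete numeric matrix (samples x features); no missing
#'   values (impute upstream).
#' @param y training labels; at least two classes must be present.
#' @return a fitted predictor; use [predict()] on new data.
#' @export
fit_predictor <- function(spec, x, y) {
  stopifnot(inherits(spec, "predictor_spec"), is.matrix(x))
  if (nrow(x) != length(y)) stop("labels must match matrix rows")
  if (anyNA(x)) stop("training matrix contains missing values")
  yf <- as_population_factor(y)
  yf <- droplevels(yf)
  if (nlevels(yf) < 2L) stop("training set contains a single class")
  fit <- switch(spec$name,
    smo = fit_smo(x, yf, spec$C),
    ib1 = fit_ib1(x, yf),
    dagging = fit_dagging(x, yf, spec),
    random_forest = fit_rf(x, yf, spec)
  )
  fit$spec <- spec
  fit$n_features <- ncol(x)
  fit$levels <- levels(yf)
  suffix <- c(smo = "smo", ib1 = "ib1", dagging = "dagging",
              random_forest = "rf")[[spec$name]]
  class(fit) <- c(paste0("aim_", suffix), "aim_predictor", class(fit))
  fit
}

check_newdata <- function(object, newx) {
  if (!is.matrix(newx)) newx <- as.matrix(newx)
  if (ncol(newx) != object$n_features) {
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 object$n_features, ncol(newx)))
  }
  newx
}

# ---- one-vs-one linear SVM ------------------------------------------------

fit_smo <- function(x, y, C) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1  # constant features pass through unscaled
  xs <- scale(x, center = mu, scale = sdv)
  lev <- levels(y)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    e1071::svm(xs[idx, , drop = FALSE], factor(y[idx], levels = pr),
               kernel = "linear", cost = C, scale = FALSE)
  })
  list(models = models, pairs = pairs, center = mu, scale = sdv)
}

#' @export
predict.aim_smo <- function(object, newdata, ...) {
  newx <- check_newdata(object, newdata)
  xs <- scale(newx, center = object$center, scale = object$scale)
  lev <- object$levels
  votes <- matrix(0L, nrow(xs), length(lev), dimnames = list(NULL, lev))
  for (i in seq_along(object$models)) {
    pred <- as.character(predict(object$models[[i]], xs))
    for (lab in object$pairs[[i]]) {
      votes[, lab] <- votes[, lab] + (pred == lab)
    }
  }
  # which.max over columns in sorted level order: ties fall to the
  # lexicographically smallest label
  lev[apply(votes, 1, which.max)]
}

# ---- 1-nearest-neighbour --------------------------------------------------

fit_ib1 <- function(x, y) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant feature normalizes to 0
  xn <- sweep(sweep(x, 2, lo), 2, rng, "/")
  list(train = xn, train_labels = as.character(y), lo = lo, rng = rng)
}

#' @export
predict.aim_ib1 <- function(object, newdata, ...) {
  newx <- check_newdata(object, newdata)
  xn <- sweep(sweep(newx, 2, object$lo), 2, object$rng, "/")
  tr <- object$train
  # squared Euclidean distances, test x train
  d2 <- outer(rowSums(xn^2), rowSums(tr^2), "+") - 2 * xn %*% t(tr)
  # which.min takes the earliest training index on exact distance ties
  object$train_labels[apply(d2, 1, which.min)]
}

# ---- dagging --------------------------------------------------------------

fit_dagging <- function(x, y, spec) {
  n <- nrow(x)
  k <- spec$k_subsets
  if (k > n) stop("more dagging subsets than training samples")
  set.seed(spec$seed)
  # random disjoint near-equal-size subsets covering the training set
  part <- split(sample.int(n), rep_len(seq_len(k), n))
  members <- lapply(part, function(idx) {
    ys <- droplevels(y[idx])
    if (nlevels(ys) < 2L) {
      # degenerate subset: constant base predictor
      list(constant = as.character(ys[1]))
    } else {
      fit_predictor(predictor_spec("smo", C = spec$C), x[idx, , drop = FALSE],
                    ys)
    }
  })
  list(members = members)
}

#' @export
predict.aim_dagging <- function(object, newdata, ...) {
  newx <- check_newdata(object, newdata)
  lev <- object$levels
  votes <- matrix(0L, nrow(newx), length(lev), dimnames = list(NULL, lev))
  for (mem in object$members) {
    pred <- if (!is.null(mem$constant)) rep(mem$constant, nrow(newx))
            else predict(mem, newx)
    for (lab in unique(pred)) {
      votes[, lab] <- votes[, lab] + (pred == lab)
    }
  }
  lev[apply(votes, 1, which.max)]  # ties to smallest label, as for smo
}

# ---- random forest --------------------------------------------------------

fit_rf <- function(x, y, spec) {
  set.seed(spec$seed)
  model <- randomForest::randomForest(
    x, y, ntree = spec$n_trees, mtry = max(1L, floor(sqrt(ncol(x))))
  )
  list(model = model)
}

#' @export
predict.aim_rf <- function(object, newdata, ...) {
  newx <- check_newdata(object, newdata)
  as.character(predict(object$model, newx))
}
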