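# Stratified splitting, accuracy bookkeeping, repeated splits and
# per-group minor-allele frequencies.

test_that("the 15% stratified split reproduces the nine benchmark group counts", {
  labels <- rep(names(table1_sizes), table1_sizes)
  idx <- stratified_split(labels, split_spec(0.15, seed = 1))
  test_counts <- table(labels[idx$test])[names(table1_sizes)]
  expect_equal(as.vector(test_counts), as.vector(table1_test))
  expect_equal(length(idx$test), 209L)
  expect_equal(length(idx$train), 1188L)
  train_counts <- table(labels[idx$train])[names(table1_sizes)]
  expect_equal(as.vector(train_counts),
               as.vector(table1_sizes - table1_test))
})

test_that("half-way allocations round to even", {
  # 110 * 0.15 = 16.5 -> 16; 87 * 0.15 = 13.05 -> 13; 165 * 0.15 = 24.75 -> 25
  expect_equal(round_half_even(c(16.5, 13.05, 24.75, 15.5)),
               c(16L, 13L, 25L, 16L))
  labels <- rep(c("A", "B"), c(110, 87))
  idx <- stratified_split(labels, split_spec(0.15, seed = 5))
  expect_equal(as.vector(table(labels[idx$test])), c(16L, 13L))
})

test_that("splits conserve samples, are seed-deterministic, and guard degenerate groups", {
  labels <- rep(c("A", "B", "C"), c(40, 25, 12))
  s1 <- stratified_split(labels, split_spec(0.2, seed = 9))
  s2 <- stratified_split(labels, split_spec(0.2, seed = 9))
  expect_identical(s1, s2)
  expect_equal(sort(c(s1$train, s1$test)), seq_along(labels))
  expect_equal(length(intersect(s1$train, s1$test)), 0L)

  # tiny fraction: all groups allocate zero test samples
  s0 <- stratified_split(labels, split_spec(1e-4, seed = 9))
  expect_equal(length(s0$test), 0L)

  # a group whose allocation swallows it entirely is an error
  expect_error(stratified_split(rep(c("A", "B"), c(40, 1)),
                                split_spec(0.6, seed = 1)),
               "no training samples")
})

test_that("evaluation reports satisfy the accuracy identities", {
  actual <- c("A", "A", "A", "B", "B", "C")
  pred <- c("A", "B", "A", "B", "B", "A")
  rep <- evaluation_report(actual, pred)
  expect_equal(unname(rep$per_group_accuracy),
               c(2 / 3, 1, 0))
  expect_equal(rep$total_accuracy, 4 / 6)
  # Q * sum(N_i) = sum(T_i) exactly, and Q is the N_i-weighted mean of Q_i
  expect_equal(rep$total_accuracy * sum(rep$N_i), sum(rep$T_i))
  expect_equal(rep$total_accuracy,
               sum(rep$per_group_accuracy * rep$N_i) / sum(rep$N_i))
  expect_equal(unname(rowSums(rep$confusion)[names(rep$N_i)]),
               unname(rep$N_i))
})

test_that("cross-validation predicts every sample exactly once", {
  d <- toy_classes(n_per = 20, n_classes = 3, n_noise = 5, seed = 149)
  rep <- cross_validate(d$x, d$labels, predictor_spec("ib1"),
                        n_folds = 5, seed = 3)
  expect_equal(sum(rep$N_i), nrow(d$x))
  expect_equal(sum(rep$confusion), nrow(d$x))
  fold <- attr(rep, "fold")
  expect_equal(sort(unique(fold)), 1:5)
  # stratified: each class spread over all folds
  expect_true(all(table(d$labels, fold) >= 1))
  expect_error(cross_validate(d$x, d$labels, predictor_spec("ib1"),
                              n_folds = 25, seed = 3),
               "fewer")
})

test_that("a label-leak feature yields perfect accuracy; a majority vote matches the hand tally", {
  labels <- rep(c("A", "B", "C", "D"), each = 10)
  leak <- as.integer(factor(labels))
  x <- cbind(leak = leak, leak2 = leak)
  storage.mode(x) <- "double"
  rep <- cross_validate(x, labels, predictor_spec("ib1"), n_folds = 5, seed = 1)
  expect_equal(rep$total_accuracy, 1)
  expect_true(all(rep$per_group_accuracy == 1))

  # 20-sample fixture, majority class share 11/20: a constant predictor
  # scores exactly that
  labels20 <- rep(c("maj", "min"), c(11, 9))
  rep20 <- evaluation_report(labels20, rep("maj", 20))
  expect_equal(rep20$total_accuracy, 11 / 20)
})

test_that("train/test evaluation enforces disjointness", {
  d <- toy_classes(n_per = 15, n_classes = 3, n_noise = 5, seed = 151)
  idx <- stratified_split(d$labels, split_spec(0.2, seed = 7))
  rep <- evaluate_split(d$x, d$labels, idx$train, idx$test,
                        predictor_spec("smo"))
  expect_equal(sum(rep$N_i), length(idx$test))
  expect_error(
    evaluate_split(d$x, d$labels, idx$train, c(idx$test, idx$train[1]),
                   predictor_spec("smo")),
    "overlap"
  )
})

test_that("minor-allele frequencies match hand computation and truth", {
  x <- rbind(c(0L, 2L), c(1L, 2L), c(2L, NA), c(1L, 0L))
  colnames(x) <- c("s1", "s2")
  maf <- minor_allele_frequency(x, rep("G1", 4))
  # s1: (0+1+2+1) / 8 = 0.5; s2: (2+2+0) / 6
  expect_equal(unname(maf["G1", ]), c(0.5, 4 / 6))

  # all genotypes 0 -> frequency 0; all missing -> NA
  x2 <- cbind(rep(0L, 3), rep(NA_integer_, 3))
  maf2 <- minor_allele_frequency(x2, rep("G", 3))
  expect_equal(unname(maf2[1, 1]), 0)
  expect_true(is.na(maf2[1, 2]))

  # complement symmetry: recoding with the major allele mirrors the frequency
  set.seed(157)
  x3 <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  labels3 <- rep(c("A", "B"), each = 10)
  expect_equal(minor_allele_frequency(2L - x3, labels3),
               1 - minor_allele_frequency(x3, labels3))
})

test_that("repeated splits summarize per-repetition accuracies", {
  d <- simulate_genotypes(sim_config(
    list(population_spec("P1", 40L, 1L), population_spec("P2", 40L, 2L),
         population_spec("P3", 40L, 3L)),
    n_snps = 60L, n_aims = 20L, aim_mode = "cluster", seed = 163L
  ))
  s <- repeat_splits(d$genotypes, d$labels, split_spec(0.15, seed = 11),
                     n_reps = 2, n_snps = 10, n_folds = 5)
  expect_equal(nrow(s$repetitions), 2L)
  expect_true(all(s$repetitions$cv_accuracy >= 0 &
                  s$repetitions$cv_accuracy <= 1))
  expect_gte(s$sd_test, 0)

  # a single repetition reports sd = 0 by convention
  s1 <- repeat_splits(d$genotypes, d$labels, split_spec(0.15, seed = 11),
                      n_reps = 1, n_snps = 10, n_folds = 5)
  expect_equal(s1$sd_cv, 0)
  expect_equal(s1$sd_test, 0)
  # same split seed -> same first repetition
  expect_equal(s1$repetitions$test_accuracy, s$repetitions$test_accuracy[1])
})

test_that("modal imputation uses training rows only", {
  x <- rbind(c(0L, 2L), c(0L, 2L), c(NA, 2L), c(2L, NA), c(2L, 0L))
  # training rows 1:3: column 1 mode is 0; column 2 mode is 2
  out <- impute_modal(x, train = 1:3)
  expect_equal(out[3, 1], 0L)
  expect_equal(out[4, 2], 2L)
  expect_false(anyNA(out))
  # tie in modal counts resolves to the smallest status
  x2 <- matrix(c(0L, 2L, NA), 3, 1)
  expect_equal(impute_modal(x2)[3, 1], 0L)
  # all-missing training slice warns and imputes 0
  x3 <- matrix(c(NA, NA, 1L), 3, 1)
  expect_warning(out3 <- impute_modal(x3, train = 1:2), "imputed to 0")
  expect_equal(out3[1, 1], 0L)
})
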