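# Independent brute-force oracles used to cross-check the streaming
# implementations.  These are deliberately naive: explicit double loops
# over table cells, and an exhaustive re-evaluation of the greedy mRMR
# objective at every step.

# Pearson chi-squared by direct double summation over all cells
naive_chi_squared <- function(O) {
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  N <- sum(O)
  n_i <- rowSums(O)
  m_j <- colSums(O)
  chi2 <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      E <- n_i[i] * m_j[j] / N
      chi2 <- chi2 + (O[i, j] - E)^2 / E
    }
  }
  chi2
}

naive_cramers_v <- function(O) {
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  if (nrow(O) < 2 || ncol(O) < 2) return(0)
  sqrt((naive_chi_squared(O) / sum(O)) / min(nrow(O) - 1, ncol(O) - 1))
}

# plug-in mutual information by explicit summation over the joint table
naive_mi <- function(x, y, base = 2) {
  n <- length(x)
  tab <- table(x, y)
  out <- 0
  for (a in rownames(tab)) {
    for (b in colnames(tab)) {
      pab <- tab[a, b] / n
      if (pab == 0) next
      pa <- sum(tab[a, ]) / n
      pb <- sum(tab[, b]) / n
      out <- out + pab * log(pab / (pa * pb)) / log(base)
    }
  }
  out
}

# exhaustive step-wise mRMR: at every round, score every remaining
# candidate from scratch with naive_mi and pick the best (lowest index
# on ties)
naive_mrmr_order <- function(x, labels, n_select = ncol(x)) {
  m <- ncol(x)
  selected <- integer(0)
  remaining <- seq_len(m)
  for (h in seq_len(n_select)) {
    best <- NA_integer_; best_score <- -Inf
    for (j in remaining) {
      d <- naive_mi(x[, j], labels)
      r <- if (length(selected) == 0) 0
           else mean(vapply(selected, function(i) naive_mi(x[, j], x[, i]),
                            numeric(1)))
      score <- d - r
      if (score > best_score + 1e-12) {
        best <- j; best_score <- score
      }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# random contingency table with no empty rows/columns
random_table <- function(k, r, max_count = 20L) {
  repeat {
    O <- matrix(sample.int(max_count + 1L, k * r, replace = TRUE) - 1L, k, r)
    if (all(rowSums(O) > 0) && all(colSums(O) > 0) && sum(O) > 0) return(O)
  }
}

# small complete genotype dataset with an informative block, for
# classifier and IFS tests
toy_classes <- function(n_per = 12L, n_classes = 4L, n_noise = 10L,
                        seed = 1L) {
  set.seed(seed)
  labels <- rep(LETTERS[seq_len(n_classes)], each = n_per)
  n <- length(labels)
  # two informative SNPs jointly encode the class
  s1 <- rep(c(0L, 0L, 2L, 2L), each = n_per)[seq_len(n)]
  s2 <- rep(c(0L, 2L, 0L, 2L), each = n_per)[seq_len(n)]
  noise <- matrix(sample(0:2, n * n_noise, replace = TRUE), n, n_noise)
  x <- cbind(s1, s2, noise)
  colnames(x) <- sprintf("snp%02d", seq_len(ncol(x)))
  list(x = x, labels = labels)
}
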