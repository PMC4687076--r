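# Population-structured genotype simulator with planted
# ancestry-informative markers (AIMs).
#
# Per-population allele frequencies follow the Balding-Nichols model:
# around an ancestral frequency p, each population draws its own
# frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and
# variance F*p*(1-p).  The differentiation parameter F plays the role of
# Fst.  Planted AIMs can instead be assigned near-fixed frequencies per
# population cluster (near 0 in some ancestral groups, near 1 in
# others), the pattern real ancestry-informative SNPs show across
# continental groups.  Genotypes are Hardy-Weinberg draws (binomial with
# two trials) from the population frequency.

#' Describe one simulated population
#'
#' @param name population label.
#' @param n_samples number of samples (>= 1).
#' @param ancestry either a single integer index into the ancestral
#'   frequency vectors (an unadmixed population), or a numeric vector of
#'   admixture weights over ancestral vectors 1..K (non-negative, sum to
#'   1 within 1e-9) for an admixed population.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, n_samples, ancestry) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("n_samples must be a count >= 1")
  }
  if (!is.numeric(ancestry) || length(ancestry) < 1L) {
    stop("ancestry must be an index or a weight vector")
  }
  if (length(ancestry) == 1L) {
    if (ancestry != round(ancestry) || ancestry < 1) {
      stop("a scalar ancestry must be a positive integer index")
    }
  } else {
    if (any(ancestry < 0)) stop("admixture weights must be non-negative")
    if (abs(sum(ancestry) - 1) > 1e-9) stop("admixture weights must sum to 1")
  }
  structure(
    list(name = name, n_samples = as.integer(n_samples), ancestry = ancestry),
    class = "population_spec"
  )
}

#' Configure a genotype simulation
#'
#' @param populations list of [population_spec()] objects.
#' @param n_snps total number of SNPs.
#' @param n_aims number of planted ancestry-informative SNPs
#'   (`<= n_snps`); the remaining SNPs are neutral.
#' @param aim_divergence Balding-Nichols differentiation F for planted
#'   AIMs, in (0, 1).
#' @param neutral_divergence differentiation for neutral SNPs, in
#'   `[0, aim_divergence)`; 0 means every unadmixed population shares
#'   the ancestral frequency exactly.
#' @param maf_range interval within (0, 0.5] from which ancestral
#'   frequencies are drawn uniformly.
#' @param missing_rate probability in `[0, 1)` that any genotype call is
#'   missing (missing-completely-at-random).
#' @param aim_mode `"balding_nichols"` draws AIM frequencies from the
#'   Balding-Nichols Beta with F = `aim_divergence`; `"cluster"` instead
#'   assigns each ancestral group, per AIM, to a low cluster (frequency
#'   uniform in `cluster_low`) or a high cluster (uniform in
#'   `cluster_high`), guaranteeing strongly divergent markers.
#' @param cluster_low,cluster_high frequency intervals for the two
#'   clusters in `"cluster"` mode.
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(populations, n_snps, n_aims,
                       aim_divergence = 0.6, neutral_divergence = 0.005,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       aim_mode = c("balding_nichols", "cluster"),
                       cluster_low = c(0.01, 0.1),
                       cluster_high = c(0.9, 0.99),
                       seed = 1L) {
  aim_mode <- match.arg(aim_mode)
  if (!is.list(populations) || length(populations) == 0L) {
    stop("populations must be a non-empty list of population_spec objects")
  }
  if (!all(vapply(populations, inherits, logical(1), "population_spec"))) {
    stop("populations must be population_spec objects")
  }
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("population names must be unique")
  if (n_aims > n_snps) stop("n_aims must not exceed n_snps")
  if (!(aim_divergence > 0 && aim_divergence < 1)) {
    stop("aim_divergence must lie in (0, 1)")
  }
  if (!(neutral_divergence >= 0 && neutral_divergence < aim_divergence)) {
    stop("neutral_divergence must lie in [0, aim_divergence)")
  }
  if (!(length(maf_range) == 2L && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2])) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop("missing_rate must lie in [0, 1)")
  }
  # number of ancestral frequency vectors implied by the specs
  k_anc <- max(vapply(populations, function(p) {
    if (length(p$ancestry) == 1L) as.integer(p$ancestry) else length(p$ancestry)
  }, integer(1)))
  structure(
    list(
      populations = populations, n_snps = as.integer(n_snps),
      n_aims = as.integer(n_aims), aim_divergence = aim_divergence,
      neutral_divergence = neutral_divergence, maf_range = maf_range,
      missing_rate = missing_rate, aim_mode = aim_mode,
      cluster_low = cluster_low, cluster_high = cluster_high,
      n_ancestral = k_anc, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# weight matrix (populations x ancestral vectors) from the specs
ancestry_weights <- function(config) {
  k <- config$n_ancestral
  W <- t(vapply(config$populations, function(p) {
    if (length(p$ancestry) == 1L) {
      w <- numeric(k); w[p$ancestry] <- 1
    } else {
      w <- c(p$ancestry, numeric(k - length(p$ancestry)))
    }
    w
  }, numeric(k)))
  rownames(W) <- vapply(config$populations, `[[`, character(1), "name")
  W
}

# Balding-Nichols draw: one frequency per ancestral population around p
rbalding_nichols <- function(k, p, f) {
  if (f == 0) return(rep(p, k))
  stats::rbeta(k, p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Draw true per-population allele frequencies
#'
#' First stage of the simulation: ancestral frequencies per SNP, then
#' per-population frequencies via the Balding-Nichols model (or direct
#' cluster assignment for AIMs in `"cluster"` mode).  Admixed
#' populations receive the weighted mean of their ancestral populations'
#' frequencies.
#'
#' @param config a [sim_config()].
#' @return numeric matrix (populations x SNPs) of the true frequency of
#'   the counted allele, with attributes `ancestral_p` (the per-SNP
#'   ancestral frequency), `ancestral_freq` (ancestral-vector x SNP
#'   frequencies) and `is_aim` (logical mask, AIMs occupying the first
#'   `n_aims` columns at this stage).  Deterministic given the seed.
#' @export
draw_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_ancestral
  m <- config$n_snps
  n_aims <- config$n_aims
  is_aim <- c(rep(TRUE, n_aims), rep(FALSE, m - n_aims))
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  anc <- matrix(0, k, m)
  for (s in seq_len(m)) {
    f <- if (is_aim[s]) config$aim_divergence else config$neutral_divergence
    if (is_aim[s] && config$aim_mode == "cluster") {
      # each ancestral group lands in a near-0 or near-1 cluster;
      # both clusters are guaranteed non-empty
      repeat {
        cl <- stats::rbinom(k, 1L, 0.5)
        if (any(cl == 0L) && any(cl == 1L)) break
      }
      lo <- stats::runif(k, config$cluster_low[1], config$cluster_low[2])
      hi <- stats::runif(k, config$cluster_high[1], config$cluster_high[2])
      anc[, s] <- ifelse(cl == 1L, hi, lo)
    } else {
      anc[, s] <- rbalding_nichols(k, p[s], f)
    }
  }
  W <- ancestry_weights(config)
  freq <- W %*% anc
  structure(freq, ancestral_p = p, ancestral_freq = anc, is_aim = is_aim)
}

#' Simulate a population-structured genotype dataset
#'
#' Draws genotypes under Hardy-Weinberg sampling (two Bernoulli trials
#' at the population frequency), plants `n_aims` informative SNPs at
#' random positions, applies missing-completely-at-random dropout, and
#' orients every SNP to minor-allele counts (columns whose counted
#' allele exceeds dataset frequency 0.5 are flipped, together with their
#' truth frequencies, so the container invariant holds).
#'
#' @param config a [sim_config()].
#' @return an object of class `aim_dataset`: `genotypes` (a
#'   [genotype_matrix()]), `labels` (per-sample population names),
#'   `truth_aims` (logical mask over SNPs) and `freq_table` (populations
#'   x SNPs true frequency of the counted allele).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freq <- draw_allele_frequencies(config)   # seeds the RNG; draws continue it
  pops <- rownames(freq)
  sizes <- vapply(config$populations, `[[`, integer(1), "n_samples")
  names(sizes) <- pops
  labels <- rep(pops, sizes)
  n <- length(labels); m <- config$n_snps

  values <- matrix(0L, n, m)
  for (g in pops) {
    rows <- which(labels == g)
    values[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2L, rep(freq[g, ], each = length(rows))),
      length(rows), m
    )
  }
  if (config$missing_rate > 0) {
    values[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }

  # scatter AIMs across the map instead of leaving them in a block
  is_aim <- attr(freq, "is_aim")
  perm <- sample.int(m)
  values <- values[, perm, drop = FALSE]
  freq <- freq[, perm, drop = FALSE]
  truth_aims <- is_aim[perm]

  # orient to minor-allele counts; alleles fixed to A (reference) /
  # G (counted), tie at 0.5 broken to the alphabetically first letter
  counted_freq <- colMeans(values, na.rm = TRUE) / 2
  counted_freq[is.nan(counted_freq)] <- 0
  flip <- counted_freq > 0.5 | abs(counted_freq - 0.5) < 1e-12
  if (any(flip)) {
    values[, flip] <- 2L - values[, flip]
    freq[, flip] <- 1 - freq[, flip]
  }
  minor <- ifelse(flip, "A", "G")
  major <- ifelse(flip, "G", "A")

  rsids <- sprintf("snp%05d", seq_len(m))
  sample_ids <- sprintf("%s_%04d", labels, unlist(lapply(sizes, seq_len)))
  samples <- data.frame(
    family_id = labels, individual_id = sample_ids,
    paternal_id = "0", maternal_id = "0", sex = 0L, phenotype = -9L,
    stringsAsFactors = FALSE
  )
  variants <- data.frame(
    chrom = "1", rsid = rsids, genetic_distance = 0,
    bp_position = seq_len(m) * 1000L,
    minor_allele = minor, major_allele = major,
    stringsAsFactors = FALSE
  )
  dimnames(freq) <- list(pops, rsids)
  structure(
    list(
      genotypes = genotype_matrix(values, samples = samples, variants = variants),
      labels = labels, truth_aims = truth_aims, freq_table = freq,
      config = config
    ),
    class = "aim_dataset"
  )
}

#' @export
print.aim_dataset <- function(x, ...) {
  cat(sprintf(
    "aim_dataset: %d samples, %d populations, %d SNPs (%d planted AIMs)\n",
    length(x$labels), length(unique(x$labels)),
    length(x$truth_aims), sum(x$truth_aims)
  ))
  invisible(x)
}

#' The nine HapMap-style population groups
#'
#' Nine groups with the sample sizes of the HapMap Phase 3 panels the
#' package's benchmark emulates (ASW 87, CEU 165, CHB/CHD/JPT 359, GIH
#' 101, LWK 110, MEX 86, MKK 184, TSI 102, YRI 203; 1397 samples in
#' total).  Seven groups are unadmixed, each with its own ancestral
#' frequency vector; ASW is modelled as 0.8 YRI-like + 0.2 CEU-like
#' admixture and MEX as 0.5 CEU-like + 0.5 East-Asian-like (a proxy for
#' its Native-American component, which has no unadmixed panel).
#'
#' @return a list of nine [population_spec()] objects.
#' @export
hapmap_like_populations <- function() {
  # ancestral vector indices: 1 CEU, 2 CHB/CHD/JPT, 3 GIH, 4 LWK,
  # 5 MKK, 6 TSI, 7 YRI
  asw <- numeric(7); asw[7] <- 0.8; asw[1] <- 0.2
  mex <- numeric(7); mex[1] <- 0.5; mex[2] <- 0.5
  list(
    population_spec("ASW", 87L, asw),
    population_spec("CEU", 165L, 1L),
    population_spec("CHB.CHD.JPT", 359L, 2L),
    population_spec("GIH", 101L, 3L),
    population_spec("LWK", 110L, 4L),
    population_spec("MEX", 86L, mex),
    population_spec("MKK", 184L, 5L),
    population_spec("TSI", 102L, 6L),
    population_spec("YRI", 203L, 7L)
  )
}

#' Benchmark simulation configuration
#'
#' The package's standard benchmark: the nine HapMap-style groups of
#' [hapmap_like_populations()], a minority of planted AIMs assigned
#' near-fixed cluster frequencies (the pattern real ancestry-informative
#' SNPs show across continental groups), and weakly differentiated
#' neutral SNPs.
#'
#' @param n_snps,n_aims dataset size; defaults 5000 SNPs with 300 AIMs.
#' @param seed RNG seed.
#' @param ... further arguments passed to [sim_config()].
#' @return a [sim_config()].
#' @export
hapmap_like_config <- function(n_snps = 5000L, n_aims = 300L, seed = 1L, ...) {
  sim_config(
    populations = hapmap_like_populations(),
    n_snps = n_snps, n_aims = n_aims,
    aim_divergence = 0.6, neutral_divergence = 0.005,
    maf_range = c(0.05, 0.5), missing_rate = 0.01,
    aim_mode = "cluster", seed = seed, ...
  )
}

#' Write a simulated dataset to disk
#'
#' Emits `<prefix>.ped` / `<prefix>.map` (via [write_ped_map()]), a
#' labels TSV (`sample_id`, `population`) and a truth TSV (`rsid`,
#' `is_aim`, one true-frequency column per population).  The PED/MAP
#' pair round-trips through [read_ped_map()] + [recode_additive()]
#' losslessly.
#'
#' @param data an `aim_dataset` from [simulate_genotypes()].
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_dataset <- function(data, prefix) {
  stopifnot(inherits(data, "aim_dataset"))
  paths <- write_ped_map(data$genotypes, prefix)
  labels_path <- paste0(prefix, ".labels.tsv")
  truth_path <- paste0(prefix, ".truth.tsv")
  utils::write.table(
    data.frame(sample_id = data$genotypes$samples$individual_id,
               population = data$labels),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- data.frame(
    rsid = data$genotypes$variants$rsid,
    is_aim = data$truth_aims,
    t(data$freq_table),
    check.names = FALSE
  )
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, labels = labels_path, truth = truth_path))
}
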