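# The standard synthetic benchmark (nine HapMap-style groups, 5000
# SNPs, 300 planted AIMs) is expensive to simulate, so acceptance tests
# share one cached copy per session.

.benchmark_cache <- new.env(parent = emptyenv())

benchmark_dataset <- function(seed = 101L) {
  key <- paste0("bench_", seed)
  if (!exists(key, envir = .benchmark_cache)) {
    assign(key, simulate_genotypes(hapmap_like_config(seed = seed)),
           envir = .benchmark_cache)
  }
  get(key, envir = .benchmark_cache)
}

# a small wide toy problem for stride/fold tests
benchmark_small <- function() {
  if (!exists("small", envir = .benchmark_cache)) {
    assign("small", toy_classes(n_per = 20, n_classes = 3, n_noise = 48,
                                seed = 211),
           envir = .benchmark_cache)
  }
  get("small", envir = .benchmark_cache)
}

# the nine group sizes of the benchmark (totals; training + test)
table1_sizes <- c(
  ASW = 87L, CEU = 165L, CHB.CHD.JPT = 359L, GIH = 101L, LWK = 110L,
  MEX = 86L, MKK = 184L, TSI = 102L, YRI = 203L
)
table1_test <- c(
  ASW = 13L, CEU = 25L, CHB.CHD.JPT = 54L, GIH = 15L, LWK = 16L,
  MEX = 13L, MKK = 28L, TSI = 15L, YRI = 30L
)
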