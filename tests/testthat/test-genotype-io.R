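# PED/MAP parsing, additive recoding and round-trip laws.

write_fixture <- function(ped_lines, map_lines) {
  prefix <- tempfile()
  writeLines(ped_lines, paste0(prefix, ".ped"))
  writeLines(map_lines, paste0(prefix, ".map"))
  prefix
}

map3 <- c("1\trs1\t0\t100", "1\trs2\t0\t200", "2\trs3\t0\t300")

test_that("PED rows parse into one allele pair per MAP variant", {
  prefix <- write_fixture(
    c("F1 S1 0 0 1 -9 A A A G G G",
      "F1 S2 0 0 2 -9 A G G G 0 0"),
    map3
  )
  r <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(dim(r$allele1), c(2L, 3L))
  expect_equal(r$variants$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(r$samples$individual_id, c("S1", "S2"))
  # "0 0" is the PLINK missing genotype
  expect_equal(r$allele1[2, 3], "0")
  expect_equal(r$allele2[2, 3], "0")
})

test_that("malformed PED input is rejected with line numbers", {
  prefix <- write_fixture(
    c("F1 S1 0 0 1 -9 A A A G",          # 4 genotype fields, 6 expected
      "F1 S2 0 0 2 -9 A G G G 0 0"),
    map3
  )
  expect_error(read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map")),
               "PED line 1")
  prefix2 <- write_fixture(c("F1 S1 0 0 1 -9 A 0 A G G G"), map3)
  expect_error(read_ped_map(paste0(prefix2, ".ped"), paste0(prefix2, ".map")),
               "half-missing")
  prefix3 <- write_fixture(c("F1 S1 0 0 1 -9 A A A G G G"),
                           c("1\trs1\t0", map3[2:3]))
  expect_error(read_ped_map(paste0(prefix3, ".ped"), paste0(prefix3, ".map")),
               "MAP line 1")
})

test_that("additive recoding counts the dataset-wide minor allele", {
  # calls {GG, GG, AG}: A appears 1 of 6 -> minor allele A, codes 0,0,1
  prefix <- write_fixture(
    c("F1 S1 0 0 0 -9 G G",
      "F1 S2 0 0 0 -9 G G",
      "F1 S3 0 0 0 -9 A G"),
    "1\trs1\t0\t100"
  )
  gm <- recode_additive(read_ped_map(paste0(prefix, ".ped"),
                                     paste0(prefix, ".map")))
  expect_equal(unname(gm$values[, 1]), c(0L, 0L, 1L))
  expect_equal(gm$variants$minor_allele, "A")
  expect_equal(gm$variants$major_allele, "G")
})

test_that("an exact allele-count tie goes to the alphabetically first letter", {
  # calls {AA, AG, GG}: A count 3 of 6 -> tie; minor = A; codes 2,1,0
  prefix <- write_fixture(
    c("F1 S1 0 0 0 -9 A A",
      "F1 S2 0 0 0 -9 A G",
      "F1 S3 0 0 0 -9 G G"),
    "1\trs1\t0\t100"
  )
  gm <- recode_additive(read_ped_map(paste0(prefix, ".ped"),
                                     paste0(prefix, ".map")))
  expect_equal(gm$variants$minor_allele, "A")
  expect_equal(unname(gm$values[, 1]), c(2L, 1L, 0L))
})

test_that("monomorphic and all-missing variants degrade gracefully", {
  prefix <- write_fixture(
    c("F1 S1 0 0 0 -9 G G 0 0",
      "F1 S2 0 0 0 -9 G G 0 0"),
    c("1\trs1\t0\t100", "1\trs2\t0\t200")
  )
  r <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_warning(expect_warning(gm <- recode_additive(r), "monomorphic"),
                 "no observed calls")
  expect_equal(unname(gm$values[, 1]), c(0L, 0L))
  expect_true(all(is.na(gm$values[, 2])))
})

test_that("recoding agrees with a brute-force allele tally on random data", {
  set.seed(31)
  d <- simulate_genotypes(sim_config(
    list(population_spec("A", 15L, 1L), population_spec("B", 15L, 2L)),
    n_snps = 40L, n_aims = 10L, missing_rate = 0.05, seed = 31L
  ))
  prefix <- tempfile()
  write_dataset(d, prefix)
  r <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  gm <- suppressWarnings(recode_additive(r))
  for (j in seq_len(ncol(gm$values))) {
    x1 <- r$allele1[, j]; x2 <- r$allele2[, j]
    obs <- x1 != "0"
    letters_j <- c(x1[obs], x2[obs])
    counts <- table(letters_j)
    if (length(counts) < 2) next
    minor <- if (counts[1] == counts[2]) sort(names(counts))[1]
             else names(sort(counts))[1]
    manual <- ifelse(obs, (x1 == minor) + (x2 == minor), NA_integer_)
    expect_equal(unname(gm$values[, j]), unname(manual))
    # column sum equals the total minor-allele count over observed calls
    expect_equal(sum(gm$values[, j], na.rm = TRUE),
                 sum(letters_j == minor))
  }
})

test_that("write -> read -> recode is the identity on simulated datasets", {
  d <- simulate_genotypes(sim_config(
    list(population_spec("A", 20L, 1L), population_spec("B", 20L, 2L),
         population_spec("C", 20L, 3L)),
    n_snps = 100L, n_aims = 20L, missing_rate = 0.03, seed = 77L
  ))
  prefix <- tempfile()
  paths <- write_dataset(d, prefix)
  expect_equal(length(readLines(paths["map"])), 100L)
  expect_equal(length(readLines(paths["ped"])), 60L)

  gm2 <- suppressWarnings(recode_additive(
    read_ped_map(paths["ped"], paths["map"])
  ))
  expect_identical(gm2$values, d$genotypes$values)

  # a second round trip is bit-identical too
  prefix2 <- tempfile()
  write_ped_map(gm2, prefix2)
  gm3 <- suppressWarnings(recode_additive(
    read_ped_map(paste0(prefix2, ".ped"), paste0(prefix2, ".map"))
  ))
  expect_identical(gm3$values, gm2$values)

  # heterozygous entries decode to one copy of each allele letter
  het <- which(d$genotypes$values == 1L, arr.ind = TRUE)[1, ]
  r <- read_ped_map(paths["ped"], paths["map"])
  pair <- sort(c(r$allele1[het[1], het[2]], r$allele2[het[1], het[2]]))
  expect_equal(pair, c("A", "G"))
})

test_that("the genotype container validates its invariants", {
  expect_error(genotype_matrix(matrix(3L, 2, 2)), "0, 1, 2 or NA")
  vals <- matrix(2L, 4, 1)  # counted-allele frequency 1 > 0.5
  expect_error(genotype_matrix(vals), "minor-allele")
})
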