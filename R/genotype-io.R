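# PLINK text PED/MAP input/output and additive (minor-allele-count)
# recoding, equivalent to `plink --recodeA`.

#' Construct a genotype matrix object
#'
#' The central container of the package: a samples x SNPs matrix of
#' minor-allele counts (0/1/2, `NA` = missing call) together with sample
#' and variant metadata.  Equivalent in content to the additive matrix
#' produced by `plink --recodeA`.
#'
#' @param values integer matrix, samples x SNPs, entries in
#'   `{0, 1, 2, NA}`.  Column names are taken as SNP identifiers and row
#'   names as sample identifiers when `samples`/`variants` are omitted.
#' @param samples data frame with columns `family_id`, `individual_id`,
#'   `paternal_id`, `maternal_id`, `sex`, `phenotype` (PED columns 1-6;
#'   sex/phenotype are opaque integer codes, passed through).
#' @param variants data frame with columns `chrom`, `rsid`,
#'   `genetic_distance`, `bp_position`, `minor_allele`, `major_allele`.
#'   The counted (minor) allele must have dataset-wide frequency at most
#'   0.5 among non-missing calls; this is checked.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, samples = NULL, variants = NULL) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  n <- nrow(values); m <- ncol(values)
  if (is.null(samples)) {
    ids <- rownames(values) %||% sprintf("sample%04d", seq_len(n))
    samples <- data.frame(
      family_id = ids, individual_id = ids,
      paternal_id = "0", maternal_id = "0",
      sex = 0L, phenotype = -9L, stringsAsFactors = FALSE
    )
  }
  if (is.null(variants)) {
    rsids <- colnames(values) %||% sprintf("snp%05d", seq_len(m))
    variants <- data.frame(
      chrom = "1", rsid = rsids, genetic_distance = 0,
      bp_position = seq_len(m), minor_allele = "G", major_allele = "A",
      stringsAsFactors = FALSE
    )
  }
  if (nrow(samples) != n) stop("sample table does not match matrix rows")
  if (nrow(variants) != m) stop("variant table does not match matrix columns")
  if (anyDuplicated(variants$rsid)) stop("rsids must be unique")
  if (anyDuplicated(samples$individual_id)) stop("individual ids must be unique")
  # minor-allele orientation: counted-allele frequency <= 0.5 (ties allowed)
  freq <- colMeans(values, na.rm = TRUE) / 2
  if (any(freq > 0.5 + 1e-9, na.rm = TRUE)) {
    stop("counted allele has frequency > 0.5 for some SNPs; not minor-allele coded")
  }
  rownames(values) <- samples$individual_id
  colnames(values) <- variants$rsid
  structure(
    list(values = values, samples = samples, variants = variants),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Read PLINK text PED and MAP files
#'
#' Parses whitespace-delimited PED/MAP into raw allele-pair records.
#' PLINK conventions: allele letter `"0"` marks a missing allele, and a
#' genotype is missing only when both alleles are `"0"`; a half-missing
#' pair such as `A 0` is malformed and rejected.
#'
#' @param ped_path,map_path file paths.
#' @return an object of class `ped_records`: sample table, variant table
#'   (chrom, rsid, genetic_distance, bp_position) and two character
#'   matrices `allele1`/`allele2` (samples x variants).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "\\s+")
  nf <- lengths(map_fields)
  if (any(nf != 4L)) {
    stop(sprintf("MAP line %d has %d fields, expected 4",
                 which(nf != 4L)[1], nf[nf != 4L][1]))
  }
  mp <- do.call(rbind, map_fields)
  variants <- data.frame(
    chrom = mp[, 1], rsid = mp[, 2],
    genetic_distance = as.numeric(mp[, 3]),
    bp_position = as.integer(mp[, 4]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(variants$rsid)) stop("duplicate rsids in MAP file")
  m <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  expected <- 6L + 2L * m
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  meta <- matrix(NA_character_, n, 6L)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(ped_lines[i]), "\\s+")[[1]]
    if (length(fields) != expected) {
      stop(sprintf(
        "PED line %d has %d fields; MAP lists %d variants so %d are expected",
        i, length(fields), m, expected
      ))
    }
    meta[i, ] <- fields[1:6]
    g <- fields[-(1:6)]
    x1 <- g[seq(1L, 2L * m, by = 2L)]
    x2 <- g[seq(2L, 2L * m, by = 2L)]
    half <- xor(x1 == "0", x2 == "0")
    if (any(half)) {
      stop(sprintf(
        "PED line %d, variant %s: half-missing call '%s %s'",
        i, variants$rsid[which(half)[1]],
        x1[which(half)[1]], x2[which(half)[1]]
      ))
    }
    a1[i, ] <- x1
    a2[i, ] <- x2
  }
  samples <- data.frame(
    family_id = meta[, 1], individual_id = meta[, 2],
    paternal_id = meta[, 3], maternal_id = meta[, 4],
    sex = suppressWarnings(as.integer(meta[, 5])),
    phenotype = suppressWarnings(as.integer(meta[, 6])),
    stringsAsFactors = FALSE
  )
  structure(
    list(samples = samples, variants = variants, allele1 = a1, allele2 = a2),
    class = "ped_records"
  )
}

#' Recode raw allele pairs to minor-allele counts
#'
#' For each variant the minor allele is the letter with the lower total
#' count over all non-missing calls in the whole dataset (a frequency
#' tie at exactly 0.5 is broken toward the alphabetically first letter);
#' each genotype becomes the number of copies of that allele.  The minor
#' allele is determined on the full dataset, before any train/test
#' split, mirroring the usual recode-then-split workflow.
#'
#' @param records a `ped_records` object from [read_ped_map()].
#' @return a [genotype_matrix()].  Monomorphic variants (a single allele
#'   observed) are coded all-0 with a warning; variants with no observed
#'   calls become all-`NA` with a warning.
#' @export
recode_additive <- function(records) {
  stopifnot(inherits(records, "ped_records"))
  a1 <- records$allele1; a2 <- records$allele2
  n <- nrow(a1); m <- ncol(a1)
  values <- matrix(NA_integer_, n, m)
  minor <- character(m); major <- character(m)
  mono <- character(0); empty <- character(0)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- x1 != "0"
    letters_j <- c(x1[obs], x2[obs])
    tally <- sort(table(letters_j))
    if (length(tally) == 0L) {
      minor[j] <- NA_character_; major[j] <- NA_character_
      empty <- c(empty, records$variants$rsid[j])
      next
    }
    if (length(tally) > 2L) {
      stop(sprintf("variant %s has more than two alleles", records$variants$rsid[j]))
    }
    if (length(tally) == 1L) {
      minor[j] <- NA_character_
      major[j] <- names(tally)[1]
      values[obs, j] <- 0L
      mono <- c(mono, records$variants$rsid[j])
      next
    }
    if (tally[[1]] == tally[[2]]) {
      mn <- sort(names(tally))[1]          # tie: alphabetically first
    } else {
      mn <- names(tally)[1]                # strictly rarer allele
    }
    mj <- setdiff(names(tally), mn)
    minor[j] <- mn; major[j] <- mj
    values[obs, j] <- (x1[obs] == mn) + (x2[obs] == mn)
  }
  if (length(mono) > 0) {
    warning(sprintf("%d monomorphic variant(s) coded all-0 (e.g. %s)",
                    length(mono), mono[1]))
  }
  if (length(empty) > 0) {
    warning(sprintf("%d variant(s) with no observed calls left all-missing (e.g. %s)",
                    length(empty), empty[1]))
  }
  variants <- records$variants
  variants$minor_allele <- minor
  variants$major_allele <- major
  genotype_matrix(values, samples = records$samples, variants = variants)
}

#' Write a genotype matrix as PLINK text PED and MAP files
#'
#' Inverse of [read_ped_map()] + [recode_additive()] up to allele-letter
#' assignment: a count of 2 becomes two copies of the minor allele, 1 a
#' heterozygous pair, 0 two copies of the major allele, and a missing
#' call the PLINK pair `0 0`.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map <- sprintf("%s\t%s\t%s\t%d", v$chrom, v$rsid,
                 format(v$genetic_distance, trim = TRUE), v$bp_position)
  writeLines(map, map_path)

  minor <- ifelse(is.na(v$minor_allele), "0", v$minor_allele)
  major <- ifelse(is.na(v$major_allele), "0", v$major_allele)
  s <- gm$samples
  con <- file(ped_path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(gm$values))) {
    g <- gm$values[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, minor, major))
    x2 <- ifelse(is.na(g), "0", ifelse(g == 2L, minor, major))
    line <- paste(
      s$family_id[i], s$individual_id[i], s$paternal_id[i], s$maternal_id[i],
      s$sex[i], s$phenotype[i],
      paste(rbind(x1, x2), collapse = " ")
    )
    writeLines(line, con)
  }
  invisible(c(ped = ped_path, map = map_path))
}
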