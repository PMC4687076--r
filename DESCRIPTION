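Package: aimsel
Title: Ancestry-Informative SNP Selection by Association Filtering,
    mRMR Ranking and Incremental Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects ancestry-informative markers (AIMs) from
    multi-population SNP genotype data and evaluates how well small
    marker panels predict population membership.  Genotypes are read
    from PLINK text PED/MAP files and recoded to minor-allele counts;
    SNPs are screened by Cramer's V association with population labels,
    ranked by minimal-redundancy-maximal-relevance (mRMR) mutual
    information, and panels of increasing size are scored by stratified
    10-fold cross-validation (incremental feature selection) with
    one-vs-one linear support vector machines, nearest-neighbour,
    dagging and random-forest classifiers.  A population-structured
    genotype simulator with planted informative markers provides
    ground-truth benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
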