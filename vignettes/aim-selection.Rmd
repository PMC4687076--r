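---
title: "Selecting ancestry-informative SNP panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting ancestry-informative SNP panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimsel)
```

## The problem

Human populations differ in the allele frequencies of a minority of
SNPs. A SNP whose frequencies diverge strongly between populations is
an *ancestry-informative marker* (AIM): a small panel of such SNPs can
predict which population a sample comes from, which is useful for
forensic ancestry inference, for detecting population stratification
in association studies, and for studying the genetic basis of
population-differentiated traits. The hard part is selecting the
panel: out of hundreds of thousands to millions of genotyped SNPs,
most carry no ancestry information, many informative ones are
redundant with each other, and a panel should be small, accurate
across *all* groups (including admixed ones), and validated on samples
never used for selection.

`aimsel` implements a complete selection-and-evaluation pipeline for
this problem:

1. **Recode** genotypes to minor-allele counts (0/1/2) from PLINK
   text PED/MAP input.
2. **Split** the samples into stratified training (85%) and
   independent test (15%) sets; everything downstream uses only the
   training slice until the final evaluation.
3. **Filter** SNPs by Cramér's V association between genotype status
   and population label, keeping V > 0.6.
4. **Rank** the candidates by mRMR (minimal redundancy, maximal
   relevance) mutual information.
5. **Grow** nested panels from the top of the ranking and score each
   by stratified 10-fold cross-validation (incremental feature
   selection, IFS); pick the panel size where the curve plateaus.
6. **Evaluate** the chosen panel once on the held-out test set.

## The statistics

**Cramér's V.** For one SNP, populations $i = 1..k$ and genotype
statuses $j = 1..r$ give an observed-count table $O_{ij}$ with row
totals $n_i$, column totals $m_j$ and total $N$. Pearson's statistic
is

$$\chi^2 = \sum_{i=1}^{k}\sum_{j=1}^{r}
  \frac{(O_{ij} - E_{ij})^2}{E_{ij}}, \qquad
  E_{ij} = \frac{n_i\, m_j}{N},$$

and $V = \sqrt{(\chi^2/N) / \min(k-1,\, r-1)} \in [0, 1]$, with 0
meaning no association and 1 a complete association. V is a pure
effect size — no p-values are involved — so the filter is independent
of sample size once frequencies stabilise.

Three numerical choices here are ours. First, $r$ counts the genotype
statuses *observed* among non-missing calls (`r_eff`), not a fixed 3;
this avoids zero expected counts for absent genotype classes and
coincides with $r = 3$ for ordinary SNPs where all three statuses
occur. Second, missing calls are excluded per SNP, so $N$ varies
across SNPs. Third, a SNP monomorphic among non-missing calls gets
$V = 0$ — the only association-free value consistent with V's range —
and is therefore filtered out. The filter keeps SNPs with V
*strictly* greater than the threshold (SNPs with $V \le 0.6$ are
removed).

**mRMR.** Relevance of SNP $f$ is its mutual information with the
population label $c$, $D = I(f, c)$; redundancy with the already
selected set $\Omega_s$ of $m$ SNPs is
$R = \tfrac1m \sum_{f_i \in \Omega_s} I(f, f_i)$. The greedy
difference scheme repeatedly selects
$\max_{f_j \in \Omega_t} [\, I(f_j, c) - \tfrac1m\sum_{f_i \in
\Omega_s} I(f_j, f_i)\,]$; the first pick maximises relevance alone.
Because genotypes (3 states) and labels are already categorical, the
maximum-likelihood plug-in MI estimate is used directly — no binning,
no small-sample bias correction, which is what the classical mRMR
program does on discrete data. Reported values are in bits; the
selected *order* is invariant to the logarithm base (both objective
terms scale by the same constant), which the test suite verifies.
Pairwise MI terms are accumulated lazily (each newly selected SNP
against the remaining candidates), so ranking the top $h$ of $n$
candidates costs $O(hn)$ MI evaluations rather than $O(n^2)$.
Score ties go to the lowest original column index, making the ranking
deterministic.

**Accuracy bookkeeping.** Per group $i$, $Q_i = T_i / N_i$ (correct
over total), and the total accuracy $Q = \sum_i T_i / \sum_i N_i$ is
the sample-weighted mean of the $Q_i$; $Q \cdot \sum N_i = \sum T_i$
holds as an exact integer identity and is asserted in the tests.

## The classifiers

Four multi-class classifiers are provided behind one
`predictor_spec()` interface:

* **smo** — soft-margin linear SVM, multi-class by one-vs-one pairwise
  coupling with majority voting; features are standardised internally
  from training statistics. The quadratic programs are solved by
  libsvm (via e1071); the classical SMO solver is a particular
  algorithm for the same convex problem, so any convergent solver
  yields the same classifier. Default cost $C = 1$.
* **ib1** — 1-nearest-neighbour under per-feature min–max
  normalisation; distance ties go to the earliest training index.
* **dagging** — the training set is partitioned at random into $k$
  disjoint near-equal subsets (default $k = 10$), one base learner
  (the smo configuration) is fitted per subset, and test samples are
  predicted by majority vote. A subset that degenerates to a single
  class contributes a constant voter.
* **random_forest** — 100 trees (configurable), each split choosing
  among $\lfloor\sqrt{M}\rfloor$ random features (randomForest).

All vote ties break to the lexicographically smallest label, so every
prediction path is deterministic given the spec's seed; smo and ib1
are deterministic outright.

## Incremental feature selection and the plateau rule

For each evaluated prefix size $i$ the top-$i$ ranked SNPs are scored
by stratified 10-fold cross-validation. The fold assignment is drawn
once per curve from the seed and reused for every $i$, so points on
the curve are paired comparisons. Stratification is used because
several groups are small relative to ten folds; a `step` argument
evaluates every `step`-th prefix when scanning all of them would be
wasteful.

Panel-size selection is codified rather than visual: mode `"max"`
returns the smallest evaluated size achieving the maximum accuracy;
mode `"plateau"` (the default in the pipeline) returns the smallest
evaluated $i$ whose total accuracy is at least $\theta$ *and* which no
later evaluated point beats by more than $\delta$. The defaults
$\theta = 0.90$, $\delta = 0.01$ encode the usual reading of an IFS
curve that "becomes stable and stays above 90%". With
$\delta = \infty$ the rule degenerates to "first $i$ reaching
$\theta$". When no size qualifies, the function returns an explicit
no-plateau result and the pipeline falls back to the `"max"` rule,
flagging the fallback.

## The synthetic benchmark

Real multi-population genotype panels are large downloads with
restricted redistribution, so the package ships a generator whose
defaults emulate the structure of the classic nine-group HapMap-style
design: groups ASW 87, CEU 165, CHB/CHD/JPT 359, GIH 101, LWK 110,
MEX 86, MKK 184, TSI 102, YRI 203 (1397 samples — the sizes that make
a stratified 15% split allocate exactly 209 test and 1188 training
samples with ties-to-even rounding). Seven groups are unadmixed, each
with its own ancestral frequency vector; ASW is modelled as 0.8
YRI-like + 0.2 CEU-like admixture, and MEX as 0.5 CEU-like + 0.5
East-Asian-like — a deliberate proxy, since the Native-American
ancestral component of MEX has no unadmixed reference panel in this
design.

Frequencies follow the Balding–Nichols model: around an ancestral
frequency $p$ (uniform on the configured minor-allele-frequency range,
default 0.05–0.5), each population draws from
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, which has mean $p$ and
variance $F\,p(1-p)$; $F$ is the single interpretable differentiation
knob (an $F_{st}$ analogue). Neutral SNPs use $F = 0.005$. For the
*planted AIMs* the benchmark configuration does not rely on a high
$F$: at $F = 0.6$ the U-shaped Beta frequently drives all populations
jointly toward 0 or 1, leaving a substantial fraction of "AIMs" with
little between-group contrast — in our measurements only about half
of Balding–Nichols draws at $F = 0.6$ exceed $V = 0.6$. Since the
benchmark's purpose is a panel of *genuinely* informative markers
with known truth, `hapmap_like_config()` instead uses
`aim_mode = "cluster"`: per AIM, each ancestral group is assigned to
a near-0 (frequency 0.01–0.1) or near-1 (0.9–0.99) cluster, both
clusters non-empty — the pattern real continental AIMs show.
`sim_config()` itself defaults to Balding–Nichols for both SNP
classes, so users can study the harder intermediate regime.

Genotypes are Hardy–Weinberg draws (binomial, two trials at the
population frequency), calls are dropped missing-completely-at-random
(default 1%), AIM positions are scattered across the map, and every
column is oriented to minor-allele counts (a frequency tie at exactly
0.5 breaks to the alphabetically first allele letter, matching the
recoder). Allele letters are fixed to A/G — arbitrary but
deterministic — and the whole dataset is a pure function of the
configuration, including its seed.

What the simulator does *not* emulate: linkage disequilibrium between
SNPs (all columns are independent given the frequencies), realistic
recombination or coalescent genealogies, genotyping-error structure,
and sex chromosomes. Passing benchmarks therefore demonstrate that
the pipeline recovers planted independent signal at realistic sample
sizes — not that real HapMap accuracies are reproduced, which would
additionally depend on LD, on the exact historical tooling, and on
1.46M-SNP scale.

## Missing data and information flow

The association filter excludes missing calls per SNP. mRMR and the
classifiers need complete vectors, so before ranking and
classification every missing call is imputed to the per-SNP modal
status *computed on the training rows only* — the minimal-assumption
choice for sparse MCAR missingness, and one that cannot leak test
labels. One conventional exception to strict train/test separation is
inherited from the standard workflow: the minor allele of each SNP is
determined on the full dataset before splitting (recode-then-split).
This is a mild form of information sharing, documented here because it
is invisible in the code path.

The pipeline (`run_aims_pipeline()`) wires the stages so that the
filter, the ranking, the IFS curve and the final model all see
training samples only; the test slice is touched exactly once.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.6 | Cramér's V cut-off; keep $V >$ threshold (unitless effect size) |
| `test_fraction` | 0.15 | per-group test allocation, ties-to-even rounding |
| `n_folds` | 10 | stratified CV folds |
| `theta`, `delta` | 0.90, 0.01 | IFS plateau rule (accuracy units) |
| `C` | 1 | SVM soft-margin cost |
| `k_subsets` | 10 | dagging partitions |
| `n_trees` | 100 | random-forest size |
| `aim_divergence` | 0.6 | Balding–Nichols $F$ for AIMs |
| `neutral_divergence` | 0.005 | $F$ for neutral SNPs |
| `missing_rate` | 0.01 | MCAR dropout probability |
| `n_reps` | 30 | repeated-split summaries |

## Problem sizes used by the tests

The bundled benchmark runs at 1397 samples × 5000 SNPs with 300
planted AIMs — large enough that the filter's retention rates, the
IFS plateau and the CV/test agreement are stable across seeds, small
enough to iterate on comfortably. The IFS curve is evaluated with
stride 5 up to prefix 60 (the plateau sits well inside that range on
this benchmark), and split-stability summaries use 5 repetitions with
fixed 50-SNP panels. Oracle-equivalence checks run at deliberately
tiny sizes (tables up to 9×3, mRMR instances of ≤8 features) where
exhaustive evaluation is exact.

## Known limitations

* No LD means simulated mRMR redundancy is driven only by shared
  population structure, which is weaker than the redundancy among
  physically linked real SNPs; real panels likely need relatively
  larger rankings for the same independence.
* Modal imputation is fine at ~1% MCAR missingness but would bias
  toward the major genotype under informative missingness.
* The plateau rule returns the *first* qualifying size; on noisy
  curves with small `step` this can sit a few SNPs before the visually
  obvious knee. Increase `delta` or use mode `"max"` when panel size
  is not at a premium.
* Admixed groups are modelled as fixed mixtures of ancestral
  frequency vectors (every individual equally admixed); real admixed
  cohorts have individual-level ancestry variance, which usually makes
  them *harder* to classify than this simulation suggests.
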