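---
title: "dermaclock: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dermaclock: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery behind `dermaclock`, the
assumptions it makes, the defaults it ships and why, and the limits of what
its synthetic validation demonstrates.

## The model

A DNAm age clock is a penalized linear model over CpG methylation
fractions ("beta values", methylated signal over total signal, in [0,1]):

$$\widehat{\mathrm{age}} = \beta_0 + \sum_j w_j \, \beta_j .$$

The package fits the elastic-net objective

$$\frac{1}{2n}\lVert y - X\beta\rVert_2^2 +
  \lambda\left(\alpha\lVert\beta\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

via `glmnet`, with predictors standardized internally and coefficients
reported on the raw beta scale, so a serialized `ClockModel` applies
directly to a normalized beta matrix. Ridge ($\alpha=0$) and lasso
($\alpha=1$) are the boundary cases; random-forest and RBF-SVM learners
are supported for model comparison but are returned as opaque
`NonlinearClock` objects, since they cannot be expressed as per-probe
weights (and published clocks are, in practice, linear). With a zero
penalty and more samples than probes the elastic net *is* ordinary least
squares, and the package solves that case exactly by `lm.fit` rather than
asking the coordinate-descent solver to approximate it.

The default elastic-net configuration is near-L1 with a tiny penalty
(`l1_fraction = 1`, `lambda = 1e-4`), the regime in which such clocks are
usually reported; the provenance stored in every clock file records the
learner, hyperparameters (including the L1 share of the penalty), seed and
probe count. Hyperparameter tuning, when requested, uses k-fold
cross-validation (default `kFolds = 50`, so roughly 5-sample folds on a
~250-sample training set): fold labels are assigned uniformly at random
(no stratification), out-of-fold predictions are pooled across folds, and
the grid point with the smallest pooled RMSE wins, ties going to the first
point in grid order. The default grid spans $\alpha \in \{0.1, \dots,
1.0\}$ and $\lambda$ log-spaced from $10^{-4}$ to $10^{1}$; the full
regularization path per $\alpha$ is fitted once per fold, so the lambda
grid is nearly free. Across learner families, `selectBestModel()` picks the
smallest CV RMSE with a declared tie order (elastic_net, ridge, lasso,
random_forest, svm_rbf) so results are reproducible.

Predicted ages are deliberately not clipped at zero: published clocks
report negative DNAm ages for very young or reprogrammed samples, and
clipping would hide a diagnostic signal.

## Preprocessing

**Quantile normalization.** Every sample's value distribution is forced
onto the reference distribution defined as the arithmetic mean of the
per-sample sorted vectors, preserving within-sample ranks. Ties receive
the mean of the reference values their rank span covers (the average-rank
convention). This tie rule is what makes the map *idempotent* — a tied
group maps to a single value whose repeated normalization reproduces
itself — and is asserted as a property test. On tie-free matrices the
result agrees with `limma::normalizeQuantiles` to 10 decimal places,
which the test suite uses as an independent oracle. A single-sample matrix
is returned unchanged with a warning (there is nothing to normalize
against); missing values must be removed first (`dropMissingProbes()`),
because rank assignment under missingness is ill-defined.

**Probe filtering.** Filters run in a fixed order — missing values,
cross-reactive probes, probes absent from the newer array platform, sex
chromosomes — with each removal count taken relative to the survivors of
the previous step. The `FilterReport` S4 class enforces the conservation
identity `n_output = n_input - sum(removals)` in its validity method, so a
malformed accounting cannot be constructed. The fixed order makes reports
comparable across runs; the sex-chromosome count in particular is
*incremental* (a chrX probe that is also cross-reactive is counted once,
under cross-reactivity).

**No batch correction.** The package deliberately exposes no batch
correction stage: empirical-Bayes batch removal before clock training
tends to absorb real age variance shared with batch and overfits the
final model to the training batches. Users who need it can correct
upstream and supply the corrected matrix.

## Ensemble feature selection

Arrays measure ~450k probes on a few hundred samples, so selection
precedes training. Three complementary learners each rank every probe:

- *penalized*: absolute coefficient of an elastic-net fit at the
  CV-chosen penalty, reported on the standardized-predictor scale so
  scores are comparable across probes;
- *boosted*: total split gain in a gradient-boosted tree ensemble
  (100 rounds, depth 4, learning rate 0.1);
- *forest*: permutation importance in a 100-tree random forest, clamped
  at zero (small negative permutation importances are noise).

The **union-importance** is defined here as the mean of the three min–max
normalized scores: it is bounded in [0,1], attains 1 only for a probe
top-ranked by all three methods, and a method with zero score range
(degenerate) contributes zero for every probe with a warning rather than
a division by zero. The candidate set is the union of five top-k lists —
top 100 per method, top 2000 by union-importance, top 400 by absolute
Pearson correlation with age — with ties broken by probe id so selection
is deterministic. Constant probes get a missing Pearson r and rank last.

**Correlation pruning.** Candidates are visited in decreasing |r| with
age (ties by probe id) and accepted only if their absolute correlation
with every already-accepted probe is at most the threshold (default 0.9).
This greedy rule keeps the more age-correlated member of each redundant
cluster and guarantees the output is pairwise bounded, which the
implementation asserts on every run. The 0.9 default reflects the usual
"highly correlated" cut in high-dimensional genomics; it is a tunable,
not a tuned, value. Constant probes are skipped entirely (they carry no
signal and their correlation is undefined).

## Balanced splitting

Skin cohorts skew old. Ages are binned into 7-year windows from the
cohort minimum; windows holding fewer than 5 samples are sent entirely to
training (they cannot be split meaningfully), other windows are split at
the training fraction (default 0.49) with rounding toward training.
Tissues listed in `forcedTrainingGroups` (default dermis, typically the
smallest compartment) bypass the windows and go wholly to training. The
split requires at least two splittable windows — with fewer, "balance"
is vacuous and the function refuses rather than silently degrading. The
assignment is seeded and *order-invariant*: windows are processed in age
order and ids sorted within each window before sampling, so permuting the
input rows cannot change the partition.

## Application statistics

The **age-acceleration residual** is the residual of the OLS regression
of DNAm age on chronological age (slope and intercept free), not the raw
difference: the regression absorbs systematic calibration offsets of the
clock so that the residual isolates per-sample acceleration. Residuals
sum to zero and are orthogonal to chronological age by construction, both
asserted in tests.

**Loess importance** regresses age on each probe's betas with local
quadratic regression (span 0.75, tricube weights) and reports
$1 - \mathrm{SSE}/\mathrm{SST}$. A smooth nonlinear age–beta relation
therefore scores at least as well as its linear fit. Span and degree are
recorded in the output's `parameters` attribute.

**Group comparisons** report the Shapiro–Wilk p-value per group as an
informational gate only — the package never auto-switches to a
nonparametric test, because silent test substitution makes analyses
irreproducible across cohorts. The default two-group test is Student's
pooled t (Welch by flag); the paired test requires aligned, equal-size
groups; three or more groups get one-way ANOVA plus pairwise t tests with
Bonferroni correction (raw p times the number of pairs, capped at 1).

**Over-representation analysis** is the upper-tail hypergeometric test
$P(X \ge k)$ with population = universe, successes = gene-set members in
the universe, draws = query list (after dropping, with a warning, query
genes outside the universe). The default multiplicity control is
Bonferroni — conservative, but the convention in the toolkits this
mirrors, which label it FDR control; Benjamini–Hochberg is available
explicitly. Gene sets come from user-supplied GMT files, keeping results
independent of any pathway-database version.

## The synthetic cohort generator

`simulateMethylome()` provides ground truth for validation. For an age
probe $j$, the mean methylation of sample $i$ is

$$\mu_{ij} = \mathrm{logit}^{-1}(a_j + b_j\,\mathrm{age}_i + t_{j,\tau(i)}),$$

with intercepts placing the mid-cohort level uniformly in (0.15, 0.85),
slopes $b_j = \pm\,\texttt{slopeScale}\cdot U(0.5,1.5)$ logit-units/year
(default scale 0.02, i.e. roughly a 0.3 beta-unit drift over the default
18–95-year span at mid-methylation), and Gaussian per-tissue offsets
(SD 0.2 logit-units) over the three skin compartments. Noise probes are
flat. Observed values are Beta-distributed with precision $\kappa$
(default 100, per-observation SD ≈ 0.05 at mid-methylation, comparable to
inter-sample scatter on real arrays). Technical replicates re-measure a
donor with an extra logit-scale wobble. The logit-linear form was chosen
because betas are bounded fractions and real age-CpGs drift smoothly and
monotonically; for moderate slopes it is locally close to the linear
beta-scale trend the clock fits.

What the generator does **not** emulate: batch structure between
datasets, probe-type chemistry differences, cell-composition shifts with
age, spatial correlation along the genome, heteroscedastic noise at
extreme methylation, and the heavy enrichment of real cohorts in old
donors. A pipeline that passes on synthetic cohorts is therefore shown to
be *correct* (it recovers planted signal under its own model), not shown
to reach any particular accuracy on real skin data.

## Validation problem sizes

The package's validation (test suite and `scripts/acceptance.R`) runs the
full pipeline on cohorts of 300 samples × 2,000 probes with 200 planted
age probes at $\kappa = 100$ — large enough that ensemble selection,
pruning, CV tuning and the balanced split all operate non-trivially,
small enough to iterate on — and checks: recall of planted probes in the
candidate set, held-out age correlation and RMSE, and the ratio of the
pipeline RMSE to an oracle fitted on the true planted probes with the
same CV-tuned learner. Filter accounting is validated on a manifest
fixture with the reference platform arithmetic (397,598 probes; 1,720
cross-reactive; 26,490 off-platform; sex probes nested in flagged
records), and cohort merging on a three-dataset composition of
40 + 146 + 322 samples.

## Numerical and degenerate-input choices

- Beta values outside [0,1] are a hard error with probe/sample
  coordinates; they indicate an upstream processing bug, not data to
  accommodate.
- Probes present in a beta matrix but absent from the manifest are kept,
  annotated intergenic with all flags false, and warned about; the
  manifest is required only for filtering and interpretation. Note the
  consequence: such probes do not survive the off-platform filter.
- Clock JSON files are written with 17 significant digits, the shortest
  representation that round-trips IEEE doubles bit-exactly.
- `predictAge` under `impute_mean` substitutes the stored training means
  for absent probes and reports how many; under the default `error`
  policy it lists the missing probes. Imputation exists because real
  450K/EPIC platform intersections routinely drop probes.
- All stochastic stages take an explicit integer seed (package default
  `20200713`); identical seeds give bit-identical results, including
  across input row permutations for the balanced split.

## Known limitations

- Feature selection in `runPipeline()` is computed on the full cohort
  before splitting (the order of operations used when a probe pool is
  reduced once and then shared); held-out metrics therefore evaluate the
  clock fit, not a fully nested selection-plus-fit procedure.
- The nonlinear learners are not serializable; a `NonlinearClock` lives
  only in the session that trained it.
- The ORA implementation tests one list against one collection; it does
  not model gene–probe multiplicity (a gene hit by several clock probes
  counts once).
- Quantile normalization assumes samples share a common underlying
  distribution; applying it across strongly different tissues flattens
  real compartment differences into the reference.
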