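# dermaclock

Tools for building and applying **skin-specific DNA methylation (DNAm) age
clocks** from Illumina-style beta-value matrices.

Epigenetic clocks predict an individual's age from the methylation levels of
a set of CpG sites as a weighted linear sum

```
DNAm age = b0 + sum_j  w_j * beta_j
```

where `beta_j` in [0,1] is the methylation fraction at CpG `j`. Pan-tissue
clocks underperform on skin, whose methylome is shaped by UV exposure and
tissue compartment (dermis, epidermis, whole skin); a skin-specific clock is
trained directly on skin cohorts. `dermaclock` implements the complete
construction and application pipeline:

- **IO / containers** — TSV beta matrices, sample tables and probe
  manifests validated and assembled into a `SummarizedExperiment`; clock
  models serialized as single JSON documents (`ClockModel` S4 class).
- **Preprocessing** — quantile normalization of beta values onto the
  mean-of-sorted reference distribution; sequential probe filtering
  (missing values, cross-reactive probes, probes absent from the newer
  array platform, sex chromosomes) with exact accounting (`FilterReport`).
- **Ensemble feature selection** — per-probe importances from a penalized
  linear model (glmnet), gradient-boosted trees (xgboost) and a 100-tree
  random forest (ranger); a *union-importance* (mean of min–max-normalized
  scores); top-k pre-selection plus Pearson age correlation; greedy pruning
  of inter-correlated probes.
- **Training** — age-balanced train/test splitting (7-year windows,
  minimum occupancy 5, dermis forced to training), k-fold (default 50)
  cross-validation of five learner families (elastic net, ridge, lasso,
  random forest, RBF-SVM), RMSE-based model selection.
- **Application** — DNAm age prediction with mean-imputation for missing
  probes, age-acceleration residuals (residual of DNAm age regressed on
  chronological age), loess-R² probe importance, genomic-region summaries,
  multi-clock probe overlaps, and group statistics (Shapiro–Wilk gate,
  Student/Welch/paired t, one-way ANOVA with Bonferroni pairwise tests).
- **Enrichment** — hypergeometric over-representation analysis of
  clock-associated gene lists against user-supplied GMT gene sets with
  Bonferroni (default) or Benjamini–Hochberg control.
- **Synthetic cohorts** — `simulateMethylome()` generates beta matrices
  with known ground truth (logit-linear age drift, tissue effects,
  technical replicates, Beta-distributed noise) so the entire pipeline is
  testable without external array data.

## Worked example

Build a clock on a simulated cohort with 50 planted age-CpGs among 500
probes, and evaluate it on the held-out partition:

```r
library(dermaclock)

sim <- simulateMethylome(nSamples = 120, nProbes = 500, nAgeProbes = 50,
                         seed = 7)
res <- runPipeline(sim$beta, sim$samples, kPerMethod = 50, kUnion = 150,
                   kPearson = 100, kFolds = 10, seed = 7)

res$model
#> ClockModel with 193 probes
#>   intercept: 52.01 years
#>   weights: 28 positive, 23 negative, 142 zero
#>   learner: elastic_net

str(res$test_metrics)
#> List of 4
#>  $ mae      : num 1.41
#>  $ rmse     : num 1.7
#>  $ r2       : num 0.994
#>  $ pearson_r: num 0.998

head(res$predictions, 3)
#>   sample_id dnam_age chronological_age
#> 1   syn0014 24.92089          25.41522
#> 2   syn0086 26.02942          24.07928
#> 3   syn0108 22.23591          21.28880
```

The held-out samples are predicted to within 1.7 years RMSE and correlate
with true age at r = 0.998 — the planted signal is strong by design; see
the methods vignette for what this does and does not demonstrate about real
cohorts. Interpretation helpers summarize the clock's probes:

```r
summ <- summarizeClockProbes(res$model, sim$manifest,
                             pearsonRank(sim$beta, sim$truth$age))
round(summ$region_percent, 1)
#>    TSS200    TSS1500       5UTR    1stExon       Body       3UTR intergenic
#>      16.6       17.6       18.1       12.4       18.1       17.1        0.0
round(summ$percent_positive, 1)   # % of clock probes hypermethylated with age
#> [1] 51.3
```

## Command line

Every pipeline stage is also a subcommand of the installed script
(`system.file("scripts", "dermaclock.R", package = "dermaclock")`):

```sh
Rscript dermaclock.R simulate --out sim --seed 3 --n-samples 120
Rscript dermaclock.R split    --samples sim/samples.tsv --out split --seed 3
Rscript dermaclock.R train    --beta train_beta.tsv --samples sim/samples.tsv --out model
Rscript dermaclock.R predict  --beta test_beta.tsv --clock model/clock.json --out pred
```

Each stage writes its output tables plus a `<stage>_report.json` recording
every resolved parameter and seed, so any stage can be replayed
identically. A YAML `--config` can supply defaults; flags override it.

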