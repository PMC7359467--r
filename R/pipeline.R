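## End-to-end clock construction: ensemble pre-selection, correlation
## pruning, age-balanced split, training and held-out evaluation.

#' Build a clock from a normalized cohort, end to end
#'
#' Runs the full construction pipeline on a normalized, filtered beta
#' matrix: (1) ensemble importance ranking and top-k pre-selection plus
#' Pearson top-k ([buildImportanceTable()], [preselectFeatures()]);
#' (2) greedy correlation pruning ([pruneCorrelated()]); (3) age-balanced
#' train/test split ([balancedSplit()]); (4) clock training on the training
#' partition ([trainClock()], optionally hyperparameter-tuned with
#' [crossValidate()] when `kFolds >= 2`); (5) held-out evaluation on the
#' test partition. Feature selection is computed on the full cohort, the
#' same order of operations used when the probe pool is reduced before
#' splitting; the held-out metrics therefore measure the clock fit, not a
#' fully nested selection.
#'
#' @param beta normalized beta matrix (probes x samples), no missing values.
#' @param samples sample table covering the matrix columns, ages known.
#' @param kPerMethod,kUnion,kPearson pre-selection top-k sizes (defaults
#'   100, 2000, 400).
#' @param threshold correlation-pruning threshold (default 0.9).
#' @param learner,hyperparameters,kFolds passed to [trainClock()] /
#'   [crossValidate()]; `kFolds = 0` (default) skips tuning and uses the
#'   learner's default hyperparameters.
#' @param splitArgs list of extra arguments for [balancedSplit()].
#' @param seed integer seed driving every stochastic stage.
#' @return list with `model`, `importance` (full table), `candidates`,
#'   `selected`, `split`, `predictions` (test-set data.frame), and
#'   `test_metrics` (`mae`, `rmse`, `r2`, `pearson_r`).
#' @export
runPipeline <- function(beta, samples, kPerMethod = 100L, kUnion = 2000L,
                        kPearson = 400L, threshold = 0.9,
                        learner = "elastic_net", hyperparameters = NULL,
                        kFolds = 0L, splitArgs = list(),
                        seed = DEFAULT_SEED) {
  age <- samples$age[match(colnames(beta), samples$sample_id)]
  if (anyNA(age))
    stop("every sample in the beta matrix needs a known age", call. = FALSE)

  tbl <- buildImportanceTable(beta, age, seed = seed)
  candidates <- suppressWarnings(
    preselectFeatures(tbl, kPerMethod = kPerMethod, kUnion = kUnion,
                      kPearson = kPearson))
  selected <- pruneCorrelated(beta[candidates, , drop = FALSE], age,
                              threshold = threshold)

  split <- do.call(balancedSplit,
                   c(list(samples = samples[match(colnames(beta),
                                                  samples$sample_id), ,
                                            drop = FALSE],
                          seed = seed), splitArgs))
  Xtr <- beta[selected, split$train, drop = FALSE]
  ageTr <- age[match(split$train, colnames(beta))]
  if (kFolds >= 2L) {
    cv <- crossValidate(Xtr, ageTr, learner = learner, kFolds = kFolds,
                        seed = seed)
    hyperparameters <- cv$best_hyperparameters
  }
  model <- trainClock(Xtr, ageTr, learner = learner,
                      hyperparameters = hyperparameters, seed = seed)

  pred <- predictAge(model, beta[, split$test, drop = FALSE])
  ageTe <- age[match(split$test, colnames(beta))]
  metrics <- computeMetrics(pred$dnam_age, ageTe)
  metrics$pearson_r <- cor(pred$dnam_age, ageTe)
  pred$chronological_age <- ageTe

  list(model = model, importance = tbl, candidates = candidates,
       selected = selected, split = split, predictions = pred,
       test_metrics = metrics)
}
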