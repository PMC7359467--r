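## Ensemble feature selection: three importance rankers (penalized linear
## model, gradient-boosted trees, random forest), Pearson age correlation,
## a union-importance combining the three, top-k pre-selection and greedy
## removal of inter-correlated probes.

DEFAULT_SEED <- 20200713L

.checkAgeMatrix <- function(X, age, minSamples) {
  validateBetaMatrix(X)
  if (anyNA(X)) stop("missing beta values not allowed here", call. = FALSE)
  if (length(age) != ncol(X))
    stop("age vector length must match sample count", call. = FALSE)
  if (anyNA(age)) stop("missing ages not allowed here", call. = FALSE)
  if (ncol(X) < minSamples)
    stop("need at least ", minSamples, " samples with known age",
         call. = FALSE)
  if (sd(age) == 0) stop("age vector is constant", call. = FALSE)
  invisible(TRUE)
}

#' Rank probes by importance for age prediction
#'
#' Scores every probe with one of three complementary learners, each fitted
#' on samples x probes with chronological age as the response:
#' \describe{
#'   \item{penalized}{elastic-net linear model (`glmnet`); score is the
#'     absolute coefficient on standardized predictors at the
#'     cross-validation-chosen penalty.}
#'   \item{boosted}{gradient-boosted trees (`xgboost`); score is the total
#'     split gain attributed to the probe.}
#'   \item{forest}{random forest with 100 trees (`ranger`); score is the
#'     permutation importance, clamped at zero.}
#' }
#'
#' @param X beta matrix (probes x samples), no missing values.
#' @param age numeric, years, one per sample.
#' @param method one of `"penalized"`, `"boosted"`, `"forest"`.
#' @param seed integer; all three learners are deterministic given the seed.
#' @return named numeric vector of non-negative scores, one per probe.
#' @export
rankImportance <- function(X, age,
                           method = c("penalized", "boosted", "forest"),
                           seed = DEFAULT_SEED) {
  method <- match.arg(method)
  .checkAgeMatrix(X, age, minSamples = 10L)
  xt <- t(X)
  score <- switch(method,
    penalized = .importancePenalized(xt, age, seed),
    boosted = .importanceBoosted(xt, age, seed),
    forest = .importanceForest(xt, age, seed))
  stats::setNames(pmax(score, 0), rownames(X))
}

.importancePenalized <- function(xt, age, seed) {
  set.seed(seed)
  nfolds <- min(10L, nrow(xt))
  cv <- glmnet::cv.glmnet(xt, age, alpha = 0.5, nfolds = nfolds,
                          standardize = TRUE)
  beta <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
  # report on the standardized-predictor scale so scores are comparable
  sds <- apply(xt, 2L, sd)
  abs(beta) * sds
}

.importanceBoosted <- function(xt, age, seed) {
  set.seed(seed)
  booster <- xgboost::xgboost(
    x = xt, y = age, nrounds = 100L, max_depth = 4L, learning_rate = 0.1,
    objective = "reg:squarederror", nthreads = 1L, verbosity = 0)
  imp <- xgboost::xgb.importance(model = booster)
  score <- stats::setNames(rep(0, ncol(xt)), colnames(xt))
  score[imp$Feature] <- imp$Gain
  score
}

.importanceForest <- function(xt, age, seed) {
  fit <- ranger::ranger(x = xt, y = age, num.trees = 100L,
                        importance = "permutation", seed = seed,
                        num.threads = 1L)
  fit$variable.importance[colnames(xt)]
}

#' Pearson correlation of each probe with age
#'
#' @param X beta matrix (probes x samples), no missing values.
#' @param age numeric, years.
#' @return named numeric vector of Pearson r in `[-1, 1]`; probes with zero
#'   variance get `NA` (and rank last in every downstream ordering).
#' @export
pearsonRank <- function(X, age) {
  .checkAgeMatrix(X, age, minSamples = 3L)
  r <- suppressWarnings(as.numeric(cor(t(X), age)))
  stats::setNames(r, rownames(X))
}

.minMaxNormalize <- function(x, label) {
  rng <- range(x)
  if (rng[2L] - rng[1L] == 0) {
    warning("method '", label, "' has zero score range; contributes 0",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Build the per-probe importance table
#'
#' Runs the three importance rankers and the Pearson correlation, then fills
#' the union-importance: the mean of the three min-max-normalized method
#' scores, a single `[0, 1]` score aggregating the ensemble.
#'
#' @param X beta matrix (probes x samples), no missing values.
#' @param age numeric, years.
#' @param seed integer passed to every stochastic learner.
#' @return data.frame with columns `probe_id`, `score_penalized`,
#'   `score_boosted`, `score_forest`, `score_union`, `pearson_r`.
#' @export
buildImportanceTable <- function(X, age, seed = DEFAULT_SEED) {
  tbl <- data.frame(
    probe_id = rownames(X),
    score_penalized = rankImportance(X, age, "penalized", seed),
    score_boosted = rankImportance(X, age, "boosted", seed),
    score_forest = rankImportance(X, age, "forest", seed),
    score_union = NA_real_,
    pearson_r = pearsonRank(X, age),
    row.names = NULL, stringsAsFactors = FALSE)
  unionImportance(tbl)
}

#' Fill the union-importance column of an importance table
#'
#' @param tbl data.frame with `score_penalized`, `score_boosted`,
#'   `score_forest` columns (see [buildImportanceTable()]).
#' @return `tbl` with `score_union` = mean of the three min-max-normalized
#'   method scores; a method whose scores are all identical contributes 0
#'   for every probe (with a warning). A probe top-ranked by all three
#'   methods attains union score 1.
#' @export
unionImportance <- function(tbl) {
  need <- c("score_penalized", "score_boosted", "score_forest")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("importance table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  norm <- vapply(need, function(cn) .minMaxNormalize(tbl[[cn]], cn),
                 numeric(nrow(tbl)))
  tbl$score_union <- rowMeans(norm)
  tbl
}

.topK <- function(ids, score, k, absolute = FALSE) {
  if (absolute) score <- abs(score)
  # NA scores (constant probes) rank last; ties broken by probe id
  o <- order(-score, ids, na.last = TRUE)
  ids[o][seq_len(min(k, length(ids)))]
}

#' Pre-select candidate probes from the importance table
#'
#' The candidate set is the union of five top-k lists: the top
#' `kPerMethod` probes of each importance method, the top `kUnion` by
#' union-importance, and the top `kPearson` by absolute Pearson correlation
#' with age. Ties are broken by probe id so the selection is deterministic.
#'
#' @param tbl importance table from [buildImportanceTable()].
#' @param kPerMethod,kUnion,kPearson top-k sizes (defaults 100, 2000, 400).
#' @return character vector of candidate probe ids, ordered by decreasing
#'   union-importance.
#' @export
preselectFeatures <- function(tbl, kPerMethod = 100L, kUnion = 2000L,
                              kPearson = 400L) {
  n <- nrow(tbl)
  if (max(kPerMethod, kUnion, kPearson) > n)
    warning("k exceeds probe count (", n, "); taking all probes for that list",
            call. = FALSE)
  ids <- tbl$probe_id
  sel <- unique(c(
    .topK(ids, tbl$score_penalized, kPerMethod),
    .topK(ids, tbl$score_boosted, kPerMethod),
    .topK(ids, tbl$score_forest, kPerMethod),
    .topK(ids, tbl$score_union, kUnion),
    .topK(ids, tbl$pearson_r, kPearson, absolute = TRUE)))
  sel[order(-tbl$score_union[match(sel, ids)], sel)]
}

#' Greedily remove inter-correlated probes
#'
#' Probes that track age also track each other; a clock does not need both
#' members of a near-duplicate pair. Candidates are visited in decreasing
#' absolute Pearson correlation with age (ties by probe id) and accepted
#' only if their absolute correlation with every already-accepted probe is
#' at most `threshold`, so the more age-correlated member of each redundant
#' cluster survives and the output is pairwise bounded by the threshold.
#'
#' @param X beta matrix restricted to candidate probes (probes x samples).
#' @param age numeric, years.
#' @param threshold maximum allowed pairwise absolute correlation, in
#'   `(0, 1]`; default 0.9.
#' @return character vector of surviving probe ids, in visit order (the
#'   most age-correlated candidate is always first).
#' @export
pruneCorrelated <- function(X, age, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  .checkAgeMatrix(X, age, minSamples = 3L)
  r <- pearsonRank(X, age)
  visit <- order(-abs(r), rownames(X), na.last = TRUE)

  # unit-scaled sample vectors: crossprod gives Pearson r directly
  n <- ncol(X)
  Z <- t(X) - matrix(rowMeans(X), n, nrow(X), byrow = TRUE)
  norms <- sqrt(colSums(Z^2))
  constant <- norms == 0
  Z <- sweep(Z, 2L, ifelse(constant, 1, norms), "/")

  accepted <- integer(0)
  for (i in visit) {
    if (constant[i]) next  # a constant probe carries no signal
    ok <- if (length(accepted) == 0L) TRUE else
      all(abs(crossprod(Z[, accepted, drop = FALSE], Z[, i])) <=
            threshold + 1e-12)
    if (ok) accepted <- c(accepted, i)
  }
  if (!length(accepted))
    stop("no probes survive correlation pruning", call. = FALSE)
  rownames(X)[accepted]
}
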