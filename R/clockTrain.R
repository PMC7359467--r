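## Age-balanced train/test splitting, k-fold cross-validated training of
## five learner families, prediction metrics, and RMSE-based model selection.

LEARNERS <- c("elastic_net", "ridge", "lasso", "random_forest", "svm_rbf")
LINEAR_LEARNERS <- c("elastic_net", "ridge", "lasso")

#' Age-balanced train/test split
#'
#' Skin methylation cohorts are enriched in older donors; splitting at
#' random would concentrate the rare young samples in one partition and
#' overfit the clock to old ages. Ages are therefore binned into windows of
#' `windowWidth` years and each sufficiently occupied window is split at
#' `trainFraction` (rounding toward training); windows holding fewer than
#' `minPerWindow` samples go entirely to training, as do all samples of the
#' `forcedTrainingGroups` tissues (by default dermis, whose sample count is
#' too small to split).
#'
#' The split is deterministic given the seed and invariant to the row order
#' of the input table.
#'
#' @param samples sample table (see [readSampleTable()]); every age must be
#'   known.
#' @param windowWidth age window width in years (default 7).
#' @param minPerWindow minimum samples for a window to be split (default 5).
#' @param trainFraction fraction of each splittable window sent to training,
#'   in (0, 1); default 0.49.
#' @param forcedTrainingGroups tissue labels placed wholly in training.
#' @param seed integer RNG seed.
#' @return list with character vectors `train` and `test`: a disjoint,
#'   exhaustive partition of `samples$sample_id`.
#' @export
balancedSplit <- function(samples, windowWidth = 7, minPerWindow = 5L,
                          trainFraction = 0.49,
                          forcedTrainingGroups = "dermis",
                          seed = DEFAULT_SEED) {
  validateSampleTable(samples)
  if (windowWidth <= 0) stop("windowWidth must be positive", call. = FALSE)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)", call. = FALSE)
  if (anyNA(samples$age))
    stop("balanced split requires a known age for every sample",
         call. = FALSE)
  absent <- setdiff(forcedTrainingGroups, samples$tissue)
  if (length(absent))
    warning("forced training group(s) not present: ",
            paste(absent, collapse = ", "), call. = FALSE)

  forced <- samples$tissue %in% forcedTrainingGroups
  train <- samples$sample_id[forced]

  eligible <- samples[!forced, , drop = FALSE]
  win <- floor((eligible$age - min(samples$age)) / windowWidth)
  counts <- table(win)
  if (sum(counts >= minPerWindow) < 2L)
    stop("fewer than 2 age windows hold >= ", minPerWindow,
         " samples; cannot balance the split", call. = FALSE)

  set.seed(seed)
  test <- character(0)
  for (w in sort(unique(win))) {
    ids <- sort(eligible$sample_id[win == w])
    if (length(ids) < minPerWindow) {
      train <- c(train, ids)
    } else {
      nTrain <- ceiling(trainFraction * length(ids))
      pick <- sample(ids, nTrain)
      train <- c(train, pick)
      test <- c(test, setdiff(ids, pick))
    }
  }
  list(train = train, test = test)
}

## ---- learner back-ends ----------------------------------------------------

# glmnet requires >= 2 predictor columns; pad single-probe designs with a
# zero column whose coefficient is necessarily 0 and dropped afterwards
.padDesign <- function(xt) {
  if (ncol(xt) >= 2L) return(list(x = xt, padded = FALSE))
  list(x = cbind(xt, `.pad.` = 0), padded = TRUE)
}

.defaultGrid <- function(learner, p) {
  lambdas <- 10^seq(1, -4, length.out = 20)  # decreasing, as glmnet expects
  switch(learner,
    elastic_net = expand.grid(alpha = seq(0.1, 1, by = 0.1),
                              lambda = lambdas),
    ridge = expand.grid(alpha = 0, lambda = lambdas),
    lasso = expand.grid(alpha = 1, lambda = lambdas),
    random_forest = expand.grid(
      mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3)))),
      min_node_size = 5L),
    svm_rbf = expand.grid(cost = c(0.25, 1, 4), gamma = 1 / p),
    stop("unsupported learner: ", learner, call. = FALSE))
}

.defaultHyperparameters <- function(learner, p) {
  switch(learner,
    elastic_net = list(alpha = 1, lambda = 1e-4),
    ridge = list(alpha = 0, lambda = 1e-2),
    lasso = list(alpha = 1, lambda = 1e-2),
    random_forest = list(mtry = max(1L, floor(p / 3)), min_node_size = 5L,
                         num_trees = 100L),
    svm_rbf = list(cost = 1, gamma = 1 / p),
    stop("unsupported learner: ", learner, call. = FALSE))
}

.fitNonlinear <- function(learner, xt, y, hp, seed) {
  if (learner == "random_forest") {
    ranger::ranger(x = xt, y = y,
                   num.trees = if (is.null(hp$num_trees)) 100L else
                     hp$num_trees,
                   mtry = min(hp$mtry, ncol(xt)),
                   min.node.size = hp$min_node_size,
                   seed = seed, num.threads = 1L)
  } else {
    set.seed(seed)
    e1071::svm(x = xt, y = y, kernel = "radial", cost = hp$cost,
               gamma = hp$gamma, type = "eps-regression")
  }
}

.predictNonlinear <- function(learner, fit, xt) {
  if (learner == "random_forest")
    predict(fit, data = xt, num.threads = 1L)$predictions
  else
    as.numeric(predict(fit, xt))
}

#' Prediction-error metrics
#'
#' @param predicted,observed numeric vectors of equal length (>= 2), years.
#' @return list with `mae` (mean absolute error), `rmse` (root mean squared
#'   error) and `r2` (1 - SSE/SST about the observed mean; `NA` with a
#'   warning when the observed values have zero variance).
#' @examples
#' computeMetrics(c(2, 2, 2), c(1, 2, 3))  # mae 2/3, rmse sqrt(2/3), r2 0
#' @export
computeMetrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2L)
    stop("predicted and observed must have equal length >= 2", call. = FALSE)
  err <- predicted - observed
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) {
    warning("observed values have zero variance; R^2 undefined",
            call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / sst
  list(mae = mae, rmse = rmse, r2 = r2)
}

#' k-fold cross-validation over a hyperparameter grid
#'
#' Fold labels are assigned uniformly at random given the seed. For every
#' grid point, the out-of-fold predictions are pooled across folds and
#' MAE / RMSE / R-squared computed on the pool; the winning grid point is the
#' one with smallest pooled RMSE (ties: first in grid order). For the
#' penalized linear learners the full regularization path per alpha is
#' fitted once per fold, so large lambda grids cost little.
#'
#' @param X beta matrix (probes x samples), no missing values.
#' @param age numeric, years.
#' @param learner one of `r paste(LEARNERS, collapse = ", ")`.
#' @param kFolds number of folds (default 50); must be between 2 and the
#'   sample count. `kFolds = n` is leave-one-out.
#' @param grid data.frame of hyperparameter combinations (columns as in the
#'   learner's default grid); `NULL` for the default.
#' @param seed integer RNG seed for fold assignment and stochastic learners.
#' @return list with `learner`, `best_hyperparameters` (list), `cv_mae`,
#'   `cv_rmse`, `cv_r2`, and `grid_metrics` (per-grid-point pooled metrics).
#' @export
crossValidate <- function(X, age, learner = "elastic_net", kFolds = 50L,
                          grid = NULL, seed = DEFAULT_SEED) {
  learner <- match.arg(learner, LEARNERS)
  .checkAgeMatrix(X, age, minSamples = 2L)
  n <- ncol(X)
  if (kFolds > n) stop("kFolds (", kFolds, ") exceeds sample count (", n,
                       ")", call. = FALSE)
  if (kFolds < 2L) stop("kFolds must be at least 2", call. = FALSE)
  if (is.null(grid)) grid <- .defaultGrid(learner, nrow(X))
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)

  xt <- t(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(kFolds), n))
  pooled <- matrix(NA_real_, n, nrow(grid))

  if (learner %in% LINEAR_LEARNERS) {
    for (f in seq_len(kFolds)) {
      inTest <- fold == f
      for (a in unique(grid$alpha)) {
        rows <- which(grid$alpha == a)
        lam <- grid$lambda[rows]
        pd <- .padDesign(xt)
        fit <- glmnet::glmnet(pd$x[!inTest, , drop = FALSE], age[!inTest],
                              alpha = a, lambda = lam, standardize = TRUE)
        pred <- predict(fit, pd$x[inTest, , drop = FALSE], s = lam,
                        exact = FALSE)
        pooled[inTest, rows] <- pred
      }
    }
  } else {
    for (f in seq_len(kFolds)) {
      inTest <- fold == f
      for (g in seq_len(nrow(grid))) {
        hp <- as.list(grid[g, , drop = FALSE])
        hp <- modifyList(.defaultHyperparameters(learner, nrow(X)), hp)
        fit <- .fitNonlinear(learner, xt[!inTest, , drop = FALSE],
                             age[!inTest], hp, seed)
        pooled[inTest, g] <- .predictNonlinear(learner, fit,
                                               xt[inTest, , drop = FALSE])
      }
    }
  }

  gm <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    m <- computeMetrics(pooled[, g], age)
    data.frame(grid[g, , drop = FALSE], mae = m$mae, rmse = m$rmse,
               r2 = m$r2, row.names = NULL)
  }))
  best <- which.min(gm$rmse)  # first minimum = first in grid order
  list(learner = learner,
       best_hyperparameters = as.list(grid[best, , drop = FALSE]),
       cv_mae = gm$mae[best], cv_rmse = gm$rmse[best], cv_r2 = gm$r2[best],
       grid_metrics = gm)
}

#' Train a DNAm age clock
#'
#' Fits one of five learner families on a beta matrix with chronological age
#' as the response. The penalized linear learners (elastic net, ridge,
#' lasso) minimize `(1/2n)||y - Xb||^2 + lambda * (alpha*||b||_1 +
#' (1-alpha)/2*||b||^2)` and return a serializable [ClockModel-class] whose
#' weights are expressed on the raw beta scale (standardization folded back
#' in), so prediction is `intercept + sum(w_j * beta_j)`. A zero penalty
#' with more samples than probes is solved exactly by ordinary least
#' squares. The random forest and RBF-SVM learners return an opaque
#' [NonlinearClock-class] honoring the same prediction interface but not
#' serializable as a linear clock.
#'
#' @param X beta matrix (probes x samples), no missing values.
#' @param age numeric, years.
#' @param learner one of `r paste(LEARNERS, collapse = ", ")`.
#' @param hyperparameters named list (e.g. `list(alpha = 1, lambda = 1e-4)`
#'   for the penalized learners); `NULL` for the learner's default.
#' @param seed integer RNG seed, recorded in provenance.
#' @return [ClockModel-class] (linear learners) or
#'   [NonlinearClock-class] (forest / SVM).
#' @export
trainClock <- function(X, age, learner = "elastic_net",
                       hyperparameters = NULL, seed = DEFAULT_SEED) {
  learner <- match.arg(learner, LEARNERS)
  .checkAgeMatrix(X, age, minSamples = 2L)
  hp <- modifyList(.defaultHyperparameters(learner, nrow(X)),
                   if (is.null(hyperparameters)) list() else hyperparameters)
  xt <- t(X)
  prov <- list(learner = learner, hyperparameters = hp, seed = seed,
               n_samples = ncol(X),
               package_version = as.character(packageVersion("dermaclock")))
  if (learner %in% LINEAR_LEARNERS) {
    # record the L1 share of the penalty alongside glmnet's (alpha, lambda)
    # so the model file documents both common parameterizations
    prov$hyperparameters$l1_fraction <- hp$alpha
  }

  if (learner %in% LINEAR_LEARNERS) {
    if (hp$lambda == 0 && ncol(X) > nrow(X)) {
      # zero-penalty elastic net IS ordinary least squares; solve it exactly
      fit <- lm.fit(cbind(`(Intercept)` = 1, xt), age)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      b0 <- cf[1L]
      w <- cf[-1L]
    } else {
      set.seed(seed)
      pd <- .padDesign(xt)
      fit <- glmnet::glmnet(pd$x, age, alpha = hp$alpha,
                            lambda = hp$lambda, standardize = TRUE,
                            thresh = 1e-10)
      cf <- as.numeric(coef(fit, s = hp$lambda))
      b0 <- cf[1L]
      w <- cf[-1L]
      if (pd$padded) w <- w[-length(w)]
    }
    names(w) <- rownames(X)
    ClockModel(b0, w, trainingMeans = rowMeans(X), provenance = prov)
  } else {
    fit <- .fitNonlinear(learner, xt, age, hp, seed)
    prov$n_probes <- nrow(X)
    new("NonlinearClock", fit = fit, probeIds = rownames(X),
        trainingMeans = rowMeans(X), provenance = prov)
  }
}

#' Select the best cross-validation result by RMSE
#'
#' @param results list of results from [crossValidate()].
#' @return the result with smallest `cv_rmse`; exact ties are broken by the
#'   declared learner order (elastic_net, ridge, lasso, random_forest,
#'   svm_rbf).
#' @export
selectBestModel <- function(results) {
  if (!is.list(results) || length(results) == 0L)
    stop("need at least one cross-validation result", call. = FALSE)
  rmse <- vapply(results, function(r) r$cv_rmse, numeric(1))
  rank <- match(vapply(results, function(r) r$learner, character(1)),
                LEARNERS)
  results[[order(rmse, rank)[1L]]]
}
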