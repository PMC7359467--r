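test_that("balancedSplit partitions, forces dermis to training, balances windows", {
  set.seed(1)
  n <- 60
  samples <- toySamples(sprintf("s%02d", 1:n),
                        age = runif(n, 20, 76),
                        tissue = rep(c("dermis", "epidermis", "whole_skin"),
                                     each = 20))
  sp <- balancedSplit(samples, seed = 4)
  expect_setequal(c(sp$train, sp$test), samples$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)
  dermis <- samples$sample_id[samples$tissue == "dermis"]
  expect_true(all(dermis %in% sp$train))

  # per-window accounting on the non-forced samples
  elig <- samples[samples$tissue != "dermis", ]
  win <- floor((elig$age - min(samples$age)) / 7)
  for (w in unique(win)) {
    ids <- elig$sample_id[win == w]
    nTr <- sum(ids %in% sp$train)
    if (length(ids) < 5) expect_equal(nTr, length(ids))
    else expect_equal(nTr, ceiling(0.49 * length(ids)))
  }
})

test_that("a single saturated window splits at the train fraction", {
  samples <- toySamples(sprintf("s%02d", 1:20), age = runif(20, 30, 33))
  # one window only -> cannot balance under the default two-window rule
  expect_error(balancedSplit(samples, forcedTrainingGroups = character(0)),
               "cannot balance")
  # widen to two windows
  samples$age <- c(runif(10, 30, 33), runif(10, 40, 43))
  sp <- balancedSplit(samples, trainFraction = 0.5,
                      forcedTrainingGroups = character(0), seed = 9)
  expect_length(sp$train, 10)
  expect_length(sp$test, 10)
})

test_that("balancedSplit is deterministic and invariant to row order", {
  set.seed(2)
  samples <- toySamples(sprintf("s%02d", 1:40), age = runif(40, 18, 88))
  sp1 <- balancedSplit(samples, seed = 11,
                       forcedTrainingGroups = character(0))
  perm <- samples[sample(nrow(samples)), ]
  sp2 <- balancedSplit(perm, seed = 11, forcedTrainingGroups = character(0))
  expect_identical(sort(sp1$train), sort(sp2$train))
  expect_identical(sort(sp1$test), sort(sp2$test))
})

test_that("computeMetrics matches hand computation and its inequalities", {
  expect_equal(computeMetrics(c(1, 2, 3), c(1, 2, 3)),
               list(mae = 0, rmse = 0, r2 = 1))
  m <- computeMetrics(c(2, 2, 2), c(1, 2, 3))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$r2, 0)
  set.seed(5)
  for (i in 1:10) {
    p <- rnorm(20); o <- rnorm(20)
    mm <- computeMetrics(p, o)
    expect_gte(mm$rmse, mm$mae)
  }
  expect_warning(zz <- computeMetrics(c(1, 2), c(3, 3)), "zero variance")
  expect_true(is.na(zz$r2))
  expect_error(computeMetrics(1, c(1, 2)), "equal length")
})

test_that("zero-penalty elastic net reproduces the least-squares oracle", {
  set.seed(8)
  n <- 40
  X <- toyBeta(runif(n * 3), 3, n)
  age <- 20 + 30 * X[1, ] - 10 * X[2, ] + rnorm(n, sd = 2)
  cm <- trainClock(X, age, "elastic_net",
                   hyperparameters = list(alpha = 1, lambda = 0))
  # normal-equations oracle
  A <- cbind(1, t(X))
  cf <- solve(crossprod(A), crossprod(A, age))
  expect_equal(unname(intercept(cm)), cf[1], tolerance = 1e-8)
  expect_equal(unname(clockWeights(cm)), unname(cf[-1]), tolerance = 1e-8)
  expect_equal(unname(trainingMeans(cm)), unname(rowMeans(X)))
})

test_that("recovered weights carry the planted slope signs", {
  sim <- simulateMethylome(nSamples = 300, nProbes = 60, nAgeProbes = 30,
                           kappa = 200, seed = 55)
  planted <- sim$truth$age_probes
  cm <- trainClock(sim$beta[planted$probe_id, ], sim$truth$age,
                   "elastic_net", hyperparameters = list(alpha = 0.5,
                                                         lambda = 1e-3))
  w <- clockWeights(cm)[planted$probe_id]
  agree <- sign(w) == sign(planted$slope)
  expect_gte(mean(agree[w != 0]), 0.9)
})

test_that("default elastic net provenance records the near-L1 configuration", {
  sim <- simulateMethylome(nSamples = 30, nProbes = 10, nAgeProbes = 4,
                           seed = 6)
  cm <- trainClock(sim$beta, sim$truth$age, "elastic_net", seed = 6)
  hp <- provenance(cm)$hyperparameters
  expect_equal(hp$l1_fraction, 1)
  expect_equal(hp$lambda, 1e-4)
  path <- file.path(withr::local_tempdir(), "clock.json")
  writeClockModel(cm, path)
  hp2 <- provenance(readClockModel(path))$hyperparameters
  expect_equal(hp2$l1_fraction, 1)
  expect_equal(hp2$lambda, 1e-4)
})

test_that("nonlinear learners honor the prediction contract but not serialization", {
  sim <- simulateMethylome(nSamples = 80, nProbes = 20, nAgeProbes = 10,
                           kappa = 300, seed = 21)
  for (lrn in c("random_forest", "svm_rbf")) {
    fit <- trainClock(sim$beta, sim$truth$age, lrn, seed = 21)
    expect_s4_class(fit, "NonlinearClock")
    pred <- predictAge(fit, sim$beta)
    expect_identical(pred$sample_id, colnames(sim$beta))
    expect_gt(cor(pred$dnam_age, sim$truth$age), 0.7)
    expect_error(writeClockModel(fit, tempfile()), "not serializable")
  }
  expect_error(trainClock(sim$beta, sim$truth$age, "boosting"),
               "'arg' should be one of")
})

test_that("noiseless linear signal cross-validates to near-zero error", {
  set.seed(12)
  n <- 40
  X <- toyBeta(runif(2 * n), 2, n)
  age <- 10 + 80 * X[1, ]
  cv <- crossValidate(X, age, "elastic_net", kFolds = 5,
                      grid = expand.grid(alpha = 1,
                                         lambda = c(1e-2, 1e-6)),
                      seed = 3)
  expect_lte(cv$cv_rmse, 0.1)
  expect_equal(cv$best_hyperparameters$lambda, 1e-6)
  expect_gte(cv$cv_rmse, cv$cv_mae)
})

test_that("k = n cross-validation equals an explicit leave-one-out loop", {
  set.seed(13)
  n <- 6
  X <- toyBeta(runif(2 * n), 2, n)
  age <- 20 + 40 * X[1, ] - 15 * X[2, ] + rnorm(n)
  grid <- expand.grid(alpha = 0.5, lambda = c(0.1, 0.01))
  cv <- crossValidate(X, age, "elastic_net", kFolds = n, grid = grid,
                      seed = 2)
  # oracle: explicit LOO with the same learner settings
  xt <- t(X)
  looPred <- matrix(NA_real_, n, nrow(grid))
  for (i in seq_len(n)) {
    fit <- glmnet::glmnet(xt[-i, ], age[-i], alpha = 0.5,
                          lambda = grid$lambda, standardize = TRUE)
    looPred[i, ] <- predict(fit, xt[i, , drop = FALSE], s = grid$lambda)
  }
  looRmse <- apply(looPred, 2, function(p) sqrt(mean((p - age)^2)))
  expect_equal(cv$cv_rmse, min(looRmse), tolerance = 1e-8)
  expect_equal(cv$grid_metrics$rmse, looRmse, tolerance = 1e-8)
  expect_error(crossValidate(X, age, "elastic_net", kFolds = n + 1),
               "exceeds sample count")
})

test_that("selectBestModel minimizes RMSE with the declared tie order", {
  r1 <- list(learner = "ridge", cv_rmse = 2.0)
  r2 <- list(learner = "lasso", cv_rmse = 3.0)
  expect_identical(selectBestModel(list(r2, r1))$learner, "ridge")
  expect_identical(selectBestModel(list(r2))$learner, "lasso")
  tie <- list(list(learner = "ridge", cv_rmse = 2.0),
              list(learner = "elastic_net", cv_rmse = 2.0))
  expect_identical(selectBestModel(tie)$learner, "elastic_net")
  expect_error(selectBestModel(list()), "at least one")
})
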