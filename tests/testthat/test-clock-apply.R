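test_that("predictAge is the affine form intercept + sum(w * beta)", {
  cm <- ClockModel(10, c(cg1 = 5, cg2 = -2))
  m <- toyBeta(c(0.5, 0.5), 2, 1, probes = c("cg1", "cg2"))
  expect_equal(predictAge(cm, m)$dnam_age, 11.5)

  # all-zero weights predict the intercept everywhere
  cm0 <- ClockModel(37.2, c(cg1 = 0, cg2 = 0))
  m2 <- toyBeta(runif(8), 2, 4, probes = c("cg1", "cg2"))
  expect_equal(predictAge(cm0, m2)$dnam_age, rep(37.2, 4))

  # linearity on random models: prediction of a convex combination
  set.seed(44)
  for (i in 1:10) {
    w <- setNames(rnorm(5), paste0("cg", 1:5))
    cm <- ClockModel(rnorm(1), w)
    a <- toyBeta(runif(5), 5, 1, probes = names(w), samples = "a")
    b <- toyBeta(runif(5), 5, 1, probes = names(w), samples = "a")
    lam <- runif(1)
    mix <- lam * a + (1 - lam) * b
    expect_equal(predictAge(cm, mix)$dnam_age,
                 lam * predictAge(cm, a)$dnam_age +
                   (1 - lam) * predictAge(cm, b)$dnam_age,
                 tolerance = 1e-10)
  }
})

test_that("missing clock probes error by default and mean-impute on request", {
  cm <- ClockModel(0, c(cg1 = 10, cg2 = 4), c(cg1 = 0.5, cg2 = 0.25))
  m <- toyBeta(0.8, 1, 1, probes = "cg1")
  expect_error(predictAge(cm, m), "absent.*cg2")
  expect_message(pred <- predictAge(cm, m, missingPolicy = "impute_mean"),
                 "1 clock probe")
  expect_equal(pred$dnam_age, 10 * 0.8 + 4 * 0.25)
})

test_that("age residuals follow the OLS normal equations", {
  # 3-point toy against the closed-form slope/intercept
  chrono <- c(20, 40, 60)
  dnam <- c(25, 38, 65)
  slope <- sum((chrono - mean(chrono)) * (dnam - mean(dnam))) /
    sum((chrono - mean(chrono))^2)
  icpt <- mean(dnam) - slope * mean(chrono)
  expect_equal(ageResiduals(dnam, chrono), dnam - (icpt + slope * chrono))

  # exact linear relation: all residuals zero
  expect_equal(ageResiduals(2 * chrono + 1, chrono), rep(0, 3))

  set.seed(9)
  for (i in 1:10) {
    ch <- runif(15, 18, 95)
    dn <- ch + rnorm(15, sd = 5)
    res <- ageResiduals(dn, ch)
    expect_lt(abs(sum(res)), 1e-9)
    expect_lt(abs(sum(res * (ch - mean(ch)))), 1e-8)  # orthogonality
  }
  expect_error(ageResiduals(c(1, 2, 3), rep(30, 3)), "constant")
  expect_error(ageResiduals(1:2, 1:2), "length >= 3")
})

test_that("predictCohort attaches chronological ages and residuals", {
  cm <- ClockModel(5, c(cg1 = 50))
  m <- toyBeta(seq(0.1, 0.9, length.out = 5), 1, 5, probes = "cg1")
  samples <- toySamples(colnames(m), age = c(20, 30, 40, 50, NA))
  res <- predictCohort(cm, m, samples)
  expect_equal(res$chronological_age, samples$age)
  known <- !is.na(samples$age)
  expect_equal(res$residual[known],
               ageResiduals(res$dnam_age[known], samples$age[known]))
  expect_true(is.na(res$residual[!known]))
})

test_that("loess importance detects smooth age relations", {
  set.seed(14)
  n <- 120
  age <- runif(n, 18, 95)
  affine <- 0.2 + 0.006 * age
  quadratic <- 0.35 + 0.00018 * (age - 55)^2 + rnorm(n, sd = 0.005)
  noise <- runif(n, 0.3, 0.7)
  X <- rbind(affine = affine, quadratic = quadratic, noise = noise)
  colnames(X) <- sprintf("s%03d", 1:n)
  imp <- loessImportance(X, age)
  r2 <- setNames(imp$r_squared, imp$probe_id)
  expect_gte(r2["affine"], 0.999)
  expect_lte(r2["noise"], 0.1)
  # nonlinear relation: loess beats the straight-line R^2 oracle
  linFit <- lm(age ~ quadratic)
  linR2 <- 1 - sum(residuals(linFit)^2) / sum((age - mean(age))^2)
  expect_gt(r2["quadratic"], linR2)
  expect_identical(imp$probe_id[1], "affine")  # sorted by importance
  expect_error(loessImportance(X, age, span = 0), "span")
})

test_that("clock probe summaries report region percentages and sign shares", {
  man <- toyManifest(paste0("cg", 1:4),
                     region = c("Body", "Body", "TSS200", "5UTR"))
  r <- c(cg1 = 0.5, cg2 = -0.2, cg3 = 0.8, cg4 = -0.1)
  s <- summarizeClockProbes(paste0("cg", 1:4), man, r)
  expect_equal(unname(s$region_percent[c("Body", "TSS200", "5UTR")]),
               c(50, 25, 25))
  expect_equal(sum(s$region_percent), 100)
  expect_equal(s$percent_positive, 50)

  # all probes in one region; unannotated probe falls back to intergenic
  s2 <- summarizeClockProbes(c("cg1", "cg2", "cgX"), man,
                             c(cg1 = 0.1, cg2 = 0.3, cgX = 0.2))
  expect_equal(unname(s2$region_percent["intergenic"]), 100 / 3)
  expect_equal(sum(s2$region_percent), 100)
})

test_that("probe overlaps compute exact pairwise and triple intersections", {
  ov <- probeOverlap(list(skin = c("a", "b", "c"), pan = c("b", "c", "d"),
                          blood = c("c", "e")))
  expect_equal(ov[["skin & pan"]]$size, 2)
  expect_identical(ov[["skin & pan & blood"]]$members, "c")
  expect_equal(ov[["pan & blood"]]$size, 1)

  same <- probeOverlap(list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(same[["x & y"]]$size, 2)
  disj <- probeOverlap(list(x = "a", y = "b"))
  expect_equal(disj[["x & y"]]$size, 0)
  expect_error(probeOverlap(list(c("a"), c("b"))), "named")
})

test_that("two-group t tests match the closed-form pooled oracle", {
  a <- c(10.2, 11.5, 9.8, 12.1, 10.9)
  b <- c(13.4, 12.8, 14.1, 13.0)
  res <- compareGroups(c(a, b), rep(c("ctrl", "trt"), c(5, 4)))
  # textbook pooled-variance t from means/SDs/n
  sp2 <- ((5 - 1) * var(a) + (4 - 1) * var(b)) / (5 + 4 - 2)
  tStat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(res$statistic, tStat)
  expect_equal(res$p_value, 2 * pt(-abs(tStat), df = 7))
  expect_identical(res$test, "t_test")
  expect_equal(unname(res$group_means), c(mean(a), mean(b)))

  # identical groups: t = 0, p = 1
  same <- compareGroups(rep(c(1, 2, 3), 2), rep(c("g1", "g2"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  welch <- compareGroups(c(a, b), rep(c("ctrl", "trt"), c(5, 4)),
                         variant = "welch")
  expect_identical(welch$test, "welch_t")
  expect_equal(welch$statistic,
               (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 4))
})

test_that("paired t equals the one-sample t on within-pair differences", {
  set.seed(19)
  pre <- rnorm(8, 50, 5)
  post <- pre + rnorm(8, -2, 1)
  res <- compareGroups(c(pre, post), rep(c("pre", "post"), each = 8),
                       design = "paired")
  d <- pre - post
  tStat <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(res$statistic, tStat)
  expect_equal(res$p_value, 2 * pt(-abs(tStat), df = 7))
  expect_error(compareGroups(c(pre, post[1:4]),
                             rep(c("pre", "post"), c(8, 4)),
                             design = "paired"), "equal group sizes")
})

test_that("multi-group comparison runs ANOVA plus Bonferroni pairwise t", {
  set.seed(26)
  g <- rep(c("a", "b", "c"), each = 6)
  v <- rnorm(18) + rep(c(0, 1, 3), each = 6)
  res <- compareGroups(v, g, design = "multi")
  fit <- anova(aov(v ~ factor(g)))
  expect_equal(res$statistic, fit$`F value`[1])
  expect_equal(res$p_value, fit$`Pr(>F)`[1])
  pw <- res$pairwise
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_bonferroni >= pw$p_raw))
  expect_true(all(pw$p_bonferroni <= 1))
  expect_equal(pw$p_bonferroni, pmin(1, pw$p_raw * 3))
  expect_length(res$shapiro_p_per_group, 3)
  expect_true(all(res$shapiro_p_per_group >= 0 &
                    res$shapiro_p_per_group <= 1))
  expect_error(compareGroups(v, rep("a", 18)), "at least 2 groups")
})
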