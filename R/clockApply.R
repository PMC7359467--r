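## Applying a fitted clock: DNAm age prediction, age-acceleration residuals,
## probe-level interpretation and group-comparison statistics.

#' Predict DNAm age from a beta matrix
#'
#' For a linear clock, `dnam_age = intercept + sum(w_j * beta_j)` over the
#' clock's probes. The input matrix must have been normalized with the same
#' procedure as the training data (caller responsibility). Probes used by
#' the clock but absent from the matrix either raise an error listing them
#' (`missingPolicy = "error"`, the default) or are imputed with the stored
#' training means (`"impute_mean"`, with a message), the usual fallback when
#' 450K-trained clocks are applied to EPIC data or vice versa.
#'
#' @param object a [ClockModel-class] or [NonlinearClock-class].
#' @param m beta matrix (probes x samples) or a `SummarizedExperiment` from
#'   [loadDataset()].
#' @param missingPolicy `"error"` or `"impute_mean"`.
#' @return data.frame with columns `sample_id` and `dnam_age` (years).
#' @examples
#' cm <- ClockModel(10, c(cg1 = 5, cg2 = -2))
#' m <- matrix(0.5, 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' predictAge(cm, m)  # 10 + 5*0.5 - 2*0.5 = 11.5 years
#' @export
setGeneric("predictAge", function(object, m, missingPolicy = "error")
  standardGeneric("predictAge"))

.resolveClockBetas <- function(probes, means, m, missingPolicy) {
  missingPolicy <- match.arg(missingPolicy, c("error", "impute_mean"))
  validateBetaMatrix(m)
  absent <- setdiff(probes, rownames(m))
  if (length(absent)) {
    if (missingPolicy == "error")
      stop("clock probe(s) absent from beta matrix: ",
           paste(head(absent, 10), collapse = ", "),
           if (length(absent) > 10) " ..." else "", call. = FALSE)
    message(length(absent), " clock probe(s) absent; imputed with training means")
  }
  B <- matrix(rep(means[probes], ncol(m)), nrow = length(probes),
              dimnames = list(probes, colnames(m)))
  present <- intersect(probes, rownames(m))
  B[present, ] <- m[present, , drop = FALSE]
  if (anyNA(B))
    stop("missing beta values among clock probes; normalize/impute first",
         call. = FALSE)
  B
}

#' @rdname predictAge
#' @export
setMethod("predictAge", "ClockModel", function(object, m,
                                               missingPolicy = "error") {
  if (is(m, "SummarizedExperiment")) m <- betaValues(m)
  B <- .resolveClockBetas(clockProbes(object), trainingMeans(object), m,
                          missingPolicy)
  age <- intercept(object) + as.numeric(crossprod(B, clockWeights(object)))
  data.frame(sample_id = colnames(m), dnam_age = age,
             stringsAsFactors = FALSE)
})

#' @rdname predictAge
#' @export
setMethod("predictAge", "NonlinearClock", function(object, m,
                                                   missingPolicy = "error") {
  if (is(m, "SummarizedExperiment")) m <- betaValues(m)
  B <- .resolveClockBetas(object@probeIds, object@trainingMeans, m,
                          missingPolicy)
  lrn <- object@provenance$learner
  age <- .predictNonlinear(lrn, object@fit, t(B))
  data.frame(sample_id = colnames(m), dnam_age = age,
             stringsAsFactors = FALSE)
})

#' DNAm age-acceleration residuals
#'
#' The DNAm age residual of a sample is its residual from the ordinary
#' least-squares regression of DNAm age on chronological age (with
#' intercept): positive means epigenetically older than expected for the
#' chronological age. Residuals sum to zero by construction.
#'
#' @param dnam numeric, predicted DNAm ages (years).
#' @param chrono numeric, chronological ages (years), same length (>= 3),
#'   non-constant.
#' @return numeric vector of residuals (years).
#' @export
ageResiduals <- function(dnam, chrono) {
  if (length(dnam) != length(chrono) || length(dnam) < 3L)
    stop("dnam and chrono must have equal length >= 3", call. = FALSE)
  if (anyNA(dnam) || anyNA(chrono))
    stop("missing values not allowed", call. = FALSE)
  if (sd(chrono) == 0)
    stop("chronological age is constant; residual model undefined",
         call. = FALSE)
  as.numeric(residuals(lm(dnam ~ chrono)))
}

#' Predict DNAm age plus residuals for an annotated cohort
#'
#' Convenience wrapper: predicts DNAm age and, for samples with known
#' chronological age (at least 3, non-constant), adds the age-acceleration
#' residual.
#'
#' @inheritParams predictAge
#' @param samples sample table matching the matrix columns (ignored when
#'   `m` is a `SummarizedExperiment`, whose `colData` is used).
#' @return data.frame `sample_id`, `dnam_age`, `chronological_age`,
#'   `residual`.
#' @export
predictCohort <- function(object, m, samples = NULL,
                          missingPolicy = "error") {
  if (is(m, "SummarizedExperiment")) {
    samples <- sampleData(m)
    m <- betaValues(m)
  }
  res <- predictAge(object, m, missingPolicy)
  res$chronological_age <- if (is.null(samples)) NA_real_ else
    samples$age[match(res$sample_id, samples$sample_id)]
  res$residual <- NA_real_
  known <- !is.na(res$chronological_age)
  if (sum(known) >= 3L && sd(res$chronological_age[known]) > 0)
    res$residual[known] <- ageResiduals(res$dnam_age[known],
                                        res$chronological_age[known])
  res
}

#' Loess R-squared importance of clock probes
#'
#' For each probe, chronological age is regressed on the probe's beta values
#' with local polynomial regression (degree 2, tricube weights); the
#' importance is the fit's R-squared, `1 - SSE/SST`. Nonlinear age-beta
#' relationships therefore score at least as well as their linear fit.
#'
#' @param X beta matrix restricted to the probes of interest
#'   (probes x samples), `n >= 10` samples.
#' @param age numeric, years.
#' @param span loess span in (0, 1]; default 0.75.
#' @param degree local polynomial degree; default 2.
#' @return data.frame `probe_id`, `r_squared`, sorted by decreasing
#'   importance; attribute `"parameters"` records span and degree.
#' @export
loessImportance <- function(X, age, span = 0.75, degree = 2L) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("span must lie in (0, 1]", call. = FALSE)
  .checkAgeMatrix(X, age, minSamples = 10L)
  sst <- sum((age - mean(age))^2)
  r2 <- vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    if (sd(x) == 0) return(0)
    fit <- tryCatch(
      loess(age ~ x, span = span, degree = degree,
            family = "gaussian",
            control = stats::loess.control(surface = "direct")),
      error = function(e) NULL)
    if (is.null(fit)) return(0)
    max(0, 1 - sum(residuals(fit)^2) / sst)
  }, numeric(1))
  out <- data.frame(probe_id = rownames(X), r_squared = r2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r_squared, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parameters") <- list(span = span, degree = degree,
                                  weights = "tricube")
  out
}

#' Summarize the genomic context and age-correlation sign of clock probes
#'
#' @param model a [ClockModel-class] (or a character vector of probe ids).
#' @param manifest probe manifest; clock probes missing from it fall back to
#'   `region = "intergenic"`.
#' @param pearsonR named numeric: Pearson r with age per clock probe (see
#'   [pearsonRank()]).
#' @return list with `region_percent` (named numeric over the region
#'   vocabulary, summing to 100) and `percent_positive` (share of probes
#'   with r > 0, in percent).
#' @export
summarizeClockProbes <- function(model, manifest, pearsonR) {
  probes <- if (is.character(model)) model else clockProbes(model)
  validateProbeManifest(manifest)
  region <- manifest$region[match(probes, manifest$probe_id)]
  region[is.na(region)] <- "intergenic"
  freq <- table(factor(region, levels = REGION_LEVELS))
  r <- pearsonR[probes]
  list(region_percent = stats::setNames(
         100 * as.numeric(freq) / length(probes), REGION_LEVELS),
       percent_positive = 100 * mean(r > 0, na.rm = TRUE))
}

#' Intersections among named probe sets
#'
#' Compares the probe memberships of two or three clocks: every pairwise
#' intersection plus, with three sets, the triple intersection.
#'
#' @param sets named list of 2 or 3 non-empty character vectors.
#' @return list of intersections, each with `sets`, `size` and sorted
#'   `members`.
#' @export
probeOverlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop("need a named list of 2 or 3 probe sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("probe sets must be named", call. = FALSE)
  if (any(lengths(sets) == 0L)) stop("probe sets must be non-empty",
                                     call. = FALSE)
  sets <- lapply(sets, unique)
  combos <- utils::combn(names(sets), 2L, simplify = FALSE)
  if (length(sets) == 3L) combos <- c(combos, list(names(sets)))
  lapply(stats::setNames(combos, vapply(combos, paste, "",
                                        collapse = " & ")), function(nm) {
    members <- sort(Reduce(intersect, sets[nm]))
    list(sets = nm, size = length(members), members = members)
  })
}

## ---- group statistics -----------------------------------------------------

.shapiroPerGroup <- function(values, groups) {
  vapply(split(values, groups), function(v) {
    if (length(v) < 3L || sd(v) == 0) {
      warning("Shapiro-Wilk skipped for a group with n < 3 or zero variance",
              call. = FALSE)
      return(NA_real_)
    }
    shapiro.test(v)$p.value
  }, numeric(1))
}

#' Compare DNAm ages (or residuals) between groups
#'
#' Implements the statistical toolkit used for intervention comparisons:
#' Shapiro-Wilk normality p-values per group (reported as an informational
#' gate, never auto-switching the test), Student or Welch two-sample t
#' tests, the paired t test for paired designs (groups aligned by order,
#' equal sizes), and one-way ANOVA followed by pairwise t tests with
#' Bonferroni correction (raw p times the number of pairs, capped at 1) for
#' more than two groups.
#'
#' @param values numeric, one value (years) per sample.
#' @param groups group labels, same length.
#' @param design `"unpaired"`, `"paired"`, or `"multi"`.
#' @param variant for two-group unpaired designs: `"student"` (pooled
#'   variance, default) or `"welch"`.
#' @return list with `test`, `statistic`, `p_value`,
#'   `shapiro_p_per_group`, `group_means`, `group_sds` and, for the multi
#'   design, `pairwise` (data.frame of Bonferroni-adjusted pairwise t
#'   tests).
#' @export
compareGroups <- function(values, groups,
                          design = c("unpaired", "paired", "multi"),
                          variant = c("student", "welch")) {
  design <- match.arg(design)
  variant <- match.arg(variant)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 samples",
                            call. = FALSE)
  base <- list(
    shapiro_p_per_group = .shapiroPerGroup(values, groups),
    group_means = vapply(split(values, groups), mean, numeric(1)),
    group_sds = vapply(split(values, groups), sd, numeric(1)))

  if (design %in% c("unpaired", "paired")) {
    if (length(lv) != 2L)
      stop("two-group designs require exactly 2 groups", call. = FALSE)
    a <- values[groups == lv[1L]]
    b <- values[groups == lv[2L]]
    if (design == "paired") {
      if (length(a) != length(b))
        stop("paired design requires equal group sizes", call. = FALSE)
      tt <- t.test(a, b, paired = TRUE)
      test <- "paired_t"
    } else {
      tt <- t.test(a, b, var.equal = (variant == "student"))
      test <- if (variant == "student") "t_test" else "welch_t"
    }
    c(list(test = test, statistic = unname(tt$statistic),
           p_value = tt$p.value), base)
  } else {
    fit <- aov(values ~ factor(groups))
    tab <- anova(fit)
    pairs <- utils::combn(lv, 2L, simplify = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(p) {
      tt <- t.test(values[groups == p[1L]], values[groups == p[2L]],
                   var.equal = TRUE)
      data.frame(group1 = p[1L], group2 = p[2L],
                 statistic = unname(tt$statistic), p_raw = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * length(pairs)),
                 stringsAsFactors = FALSE)
    }))
    c(list(test = "anova_bonferroni", statistic = tab$`F value`[1L],
           p_value = tab$`Pr(>F)`[1L], pairwise = pw), base)
  }
}
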