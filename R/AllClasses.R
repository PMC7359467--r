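#' @import methods
#' @importFrom stats coef cor lm loess lm.fit median p.adjust pf phyper
#'   predict pt quantile rbeta residuals rnorm runif sd setNames shapiro.test
#'   t.test var aov anova
#' @importFrom utils head modifyList packageVersion
NULL

#' ClockModel: a linear DNA methylation age predictor
#'
#' A fitted epigenetic clock: an intercept (years) plus one coefficient per
#' CpG probe (years per beta-unit), applied to a beta-value matrix as
#' `intercept + sum(w_j * beta_j)`. Training probe means are stored so that
#' probes absent from a new platform can optionally be mean-imputed at
#' prediction time, and a provenance list records how the model was fitted
#' (learner, hyperparameters, seed, probe count).
#'
#' @slot intercept numeric(1), years.
#' @slot weights named numeric, one coefficient per probe on the raw beta
#'   scale (years per beta-unit).
#' @slot trainingMeans named numeric in `[0,1]`, per-probe mean beta in the
#'   training data; must cover every weighted probe.
#' @slot provenance list; at minimum `learner`, `hyperparameters`, `seed`
#'   and `n_probes` (which must equal `length(weights)`).
#'
#' @seealso [trainClock()], [predictAge()], [readClockModel()],
#'   [writeClockModel()]
#' @export
setClass("ClockModel",
  representation(
    intercept = "numeric",
    weights = "numeric",
    trainingMeans = "numeric",
    provenance = "list"
  )
)

setValidity("ClockModel", function(object) {
  msg <- character(0)
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@weights) == 0L)
    msg <- c(msg, "model must have at least one probe weight")
  if (is.null(names(object@weights)) || anyDuplicated(names(object@weights)))
    msg <- c(msg, "weights must be uniquely named by probe id")
  if (is.null(names(object@trainingMeans)) ||
      !all(names(object@weights) %in% names(object@trainingMeans)))
    msg <- c(msg, "every weighted probe needs a training mean")
  mu <- object@trainingMeans
  if (length(mu) && any(!is.finite(mu) | mu < 0 | mu > 1))
    msg <- c(msg, "training probe means must lie in [0, 1]")
  np <- object@provenance$n_probes
  if (!is.null(np) && np != length(object@weights))
    msg <- c(msg, sprintf(
      "provenance records %d probes but model has %d weights",
      np, length(object@weights)))
  if (length(msg)) msg else TRUE
})

#' Construct a ClockModel
#'
#' @param intercept model intercept, years.
#' @param weights named numeric vector of per-probe coefficients
#'   (years per beta-unit).
#' @param trainingMeans named numeric vector of per-probe training mean
#'   betas; must include every weighted probe. Defaults to 0.5 for each
#'   probe when not supplied (no imputation information).
#' @param provenance list of fitting metadata; `n_probes` is filled in.
#' @return A validated [ClockModel-class] object.
#' @examples
#' cm <- ClockModel(10, c(cg1 = 5, cg2 = -2))
#' intercept(cm)
#' @export
ClockModel <- function(intercept, weights, trainingMeans = NULL,
                       provenance = list()) {
  if (is.null(trainingMeans))
    trainingMeans <- setNames(rep(0.5, length(weights)), names(weights))
  provenance$n_probes <- length(weights)
  new("ClockModel",
      intercept = as.numeric(intercept),
      weights = weights,
      trainingMeans = trainingMeans,
      provenance = provenance)
}

#' @describeIn ClockModel-class model intercept in years
#' @param object,x a `ClockModel`
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @export
setMethod("intercept", "ClockModel", function(object) object@intercept)

#' @describeIn ClockModel-class named per-probe coefficients
#' @export
setGeneric("clockWeights", function(object) standardGeneric("clockWeights"))

#' @export
setMethod("clockWeights", "ClockModel", function(object) object@weights)

#' @describeIn ClockModel-class per-probe training mean betas
#' @export
setGeneric("trainingMeans", function(object) standardGeneric("trainingMeans"))

#' @export
setMethod("trainingMeans", "ClockModel", function(object) object@trainingMeans)

#' @describeIn ClockModel-class fitting metadata list
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @export
setMethod("provenance", "ClockModel", function(object) object@provenance)

#' @describeIn ClockModel-class probe identifiers used by the clock
#' @export
setGeneric("clockProbes", function(object) standardGeneric("clockProbes"))

#' @export
setMethod("clockProbes", "ClockModel", function(object) names(object@weights))

#' @export
setMethod("show", "ClockModel", function(object) {
  cat("ClockModel with", length(object@weights), "probes\n")
  cat("  intercept:", format(object@intercept, digits = 4), "years\n")
  w <- object@weights
  cat("  weights:", sum(w > 0), "positive,", sum(w < 0), "negative,",
      sum(w == 0), "zero\n")
  lrn <- object@provenance$learner
  if (!is.null(lrn)) cat("  learner:", lrn, "\n")
})

#' NonlinearClock: an opaque non-linear age predictor
#'
#' Random-forest and RBF-kernel SVM learners produce predictors that cannot
#' be expressed as a per-probe linear weight vector. They are wrapped behind
#' the same prediction interface as [ClockModel-class] but are flagged as
#' non-serializable: [writeClockModel()] refuses them.
#'
#' @slot fit the fitted model object (a `ranger` or `svm` fit).
#' @slot probeIds probes the predictor expects, in training order.
#' @slot trainingMeans named numeric, training mean beta per probe.
#' @slot provenance list of fitting metadata.
#' @export
setClass("NonlinearClock",
  representation(
    fit = "ANY",
    probeIds = "character",
    trainingMeans = "numeric",
    provenance = "list"
  )
)

#' @export
setMethod("show", "NonlinearClock", function(object) {
  cat("NonlinearClock (", object@provenance$learner, ") with ",
      length(object@probeIds), " probes; not serializable\n", sep = "")
})

#' @export
setMethod("trainingMeans", "NonlinearClock", function(object)
  object@trainingMeans)

#' @export
setMethod("clockProbes", "NonlinearClock", function(object) object@probeIds)

#' @export
setMethod("provenance", "NonlinearClock", function(object) object@provenance)

#' FilterReport: probe-filter accounting
#'
#' Records the sequential arithmetic of the probe-filtering stage: probes
#' with missing values, cross-reactive probes, probes absent from the target
#' platform, and sex-chromosome probes are removed in that fixed order, each
#' count taken relative to the set remaining after the previous step.
#' Validity enforces conservation:
#' `nOutput == nInput - sum(removals)`.
#'
#' @slot nInput,removedMissing,removedCrossReactive,removedOffPlatform,removedSexChromosome,nOutput
#'   non-negative integer counts.
#' @seealso [filterProbes()]
#' @export
setClass("FilterReport",
  representation(
    nInput = "integer",
    removedMissing = "integer",
    removedCrossReactive = "integer",
    removedOffPlatform = "integer",
    removedSexChromosome = "integer",
    nOutput = "integer"
  )
)

setValidity("FilterReport", function(object) {
  cnt <- c(object@nInput, object@removedMissing, object@removedCrossReactive,
           object@removedOffPlatform, object@removedSexChromosome,
           object@nOutput)
  if (length(cnt) != 6L || any(is.na(cnt)))
    return("all six counts must be present")
  if (any(cnt < 0L)) return("counts must be non-negative")
  removed <- object@removedMissing + object@removedCrossReactive +
    object@removedOffPlatform + object@removedSexChromosome
  if (object@nOutput != object@nInput - removed)
    return(sprintf("conservation violated: %d input - %d removed != %d output",
                   object@nInput, removed, object@nOutput))
  TRUE
})

FilterReport <- function(nInput, removedMissing, removedCrossReactive,
                         removedOffPlatform, removedSexChromosome, nOutput) {
  new("FilterReport",
      nInput = as.integer(nInput),
      removedMissing = as.integer(removedMissing),
      removedCrossReactive = as.integer(removedCrossReactive),
      removedOffPlatform = as.integer(removedOffPlatform),
      removedSexChromosome = as.integer(removedSexChromosome),
      nOutput = as.integer(nOutput))
}

#' @export
setMethod("show", "FilterReport", function(object) {
  cat("Probe filter report\n")
  cat("  input probes:        ", object@nInput, "\n")
  cat("  - missing values:    ", object@removedMissing, "\n")
  cat("  - cross-reactive:    ", object@removedCrossReactive, "\n")
  cat("  - off-platform:      ", object@removedOffPlatform, "\n")
  cat("  - sex chromosomes:   ", object@removedSexChromosome, "\n")
  cat("  surviving probes:    ", object@nOutput, "\n")
})

#' @describeIn FilterReport-class number of surviving probes
#' @param object a `FilterReport`
#' @export
setGeneric("nOutput", function(object) standardGeneric("nOutput"))

#' @export
setMethod("nOutput", "FilterReport", function(object) object@nOutput)

#' @describeIn FilterReport-class all six counts as a named integer vector
#' @export
setGeneric("filterCounts", function(object) standardGeneric("filterCounts"))

#' @export
setMethod("filterCounts", "FilterReport", function(object)
  c(n_input = object@nInput,
    removed_missing = object@removedMissing,
    removed_cross_reactive = object@removedCrossReactive,
    removed_off_platform = object@removedOffPlatform,
    removed_sex_chromosome = object@removedSexChromosome,
    n_output = object@nOutput))
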