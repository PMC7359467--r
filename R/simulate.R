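## Synthetic methylome generation with known ground truth, plus manifest
## fixtures that reproduce probe-filter accounting exactly.

#' Simulate a skin methylation cohort with known ground truth
#'
#' Generates a beta matrix, sample table, probe manifest and truth record
#' emulating the structure of published skin cohorts: donor ages uniform
#' over `ageRange` (default 18-95 years, the span of typical skin biopsy
#' cohorts), a subset of "age probes" whose mean methylation drifts
#' logit-linearly with age plus a per-tissue offset, the remaining probes
#' flat noise, and observed betas drawn from a Beta distribution with the
#' probe's mean and precision `kappa` (shapes `mu*kappa`, `(1-mu)*kappa`),
#' which keeps every value inside (0, 1) as real beta values are.
#'
#' Age-probe intercepts are chosen so the mid-cohort methylation level is
#' uniform in (0.15, 0.85); slopes are `+/- slopeScale * U(0.5, 1.5)`
#' logit-units per year with random sign. Optional technical-replicate
#' groups re-measure one donor several times with an extra logit-scale
#' wobble of `replicateGroups$sd` per replicate.
#'
#' Identical seeds give bit-identical outputs.
#'
#' @param nSamples number of samples (default 300).
#' @param nProbes total probes (default 2000).
#' @param nAgeProbes probes with planted age signal (default 200).
#' @param ageRange two years, default `c(18, 95)`.
#' @param slopeScale logit-units per year, default 0.02 (roughly a 0.3
#'   beta-unit drift across the default age range at mid-methylation).
#' @param kappa Beta-noise precision, default 100.
#' @param tissueEffectSd SD of per-probe-per-tissue logit offsets on age
#'   probes, default 0.2.
#' @param tissues character vector of tissue labels to cycle over samples,
#'   or a named integer vector of per-tissue sample counts (must sum to
#'   `nSamples`); default the three skin compartments.
#' @param replicateGroups `NULL`, or `list(n_groups, size, sd)`: the last
#'   `n_groups * size` samples become technical replicates (each group one
#'   donor measured `size` times, default size 3).
#' @param missingRate fraction of entries set to `NA` (default 0: none).
#' @param seed integer RNG seed.
#' @return list with `beta` (matrix), `samples` (sample table), `manifest`
#'   (probe manifest, all probes autosomal/unflagged/on-platform), and
#'   `truth` (`age_probes` data.frame with per-probe logit intercept and
#'   slope, `age`, `tissue`).
#' @export
simulateMethylome <- function(nSamples = 300L, nProbes = 2000L,
                              nAgeProbes = 200L, ageRange = c(18, 95),
                              slopeScale = 0.02, kappa = 100,
                              tissueEffectSd = 0.2,
                              tissues = c("dermis", "epidermis",
                                          "whole_skin"),
                              replicateGroups = NULL, missingRate = 0,
                              seed = DEFAULT_SEED) {
  if (nAgeProbes > nProbes)
    stop("invalid config: nAgeProbes exceeds nProbes", call. = FALSE)
  if (kappa <= 0) stop("invalid config: kappa must be > 0", call. = FALSE)
  if (length(ageRange) != 2L || diff(ageRange) <= 0)
    stop("invalid config: ageRange must be an increasing pair",
         call. = FALSE)
  if (missingRate < 0 || missingRate >= 1)
    stop("invalid config: missingRate must be in [0, 1)", call. = FALSE)
  set.seed(seed)

  probeIds <- sprintf("cgS%06d", seq_len(nProbes))
  sampleIds <- sprintf("syn%04d", seq_len(nSamples))
  age <- runif(nSamples, ageRange[1L], ageRange[2L])

  if (!is.null(names(tissues)) && is.numeric(tissues)) {
    if (sum(tissues) != nSamples)
      stop("invalid config: tissue counts must sum to nSamples",
           call. = FALSE)
    tissue <- rep(names(tissues), times = tissues)
  } else {
    tissue <- rep_len(as.character(tissues), nSamples)
  }

  replicateOf <- rep(NA_character_, nSamples)
  group <- rep("none", nSamples)
  if (!is.null(replicateGroups)) {
    size <- if (is.null(replicateGroups$size)) 3L else replicateGroups$size
    nGroups <- replicateGroups$n_groups
    repSd <- if (is.null(replicateGroups$sd)) 0.05 else replicateGroups$sd
    nRep <- nGroups * size
    if (nRep > nSamples)
      stop("invalid config: replicate samples exceed nSamples",
           call. = FALSE)
    idx <- (nSamples - nRep + 1L):nSamples
    donor <- rep(seq_len(nGroups), each = size)
    # replicates share the donor's age and tissue
    base <- idx[!duplicated(donor)]
    age[idx] <- rep(age[base], each = size)
    tissue[idx] <- rep(tissue[base], each = size)
    replicateOf[idx] <- rep(sampleIds[base], each = size)
    group[idx] <- paste0("rep", donor)
  } else {
    repSd <- 0
  }

  ageProbeIdx <- seq_len(nAgeProbes)
  slope <- sample(c(-1, 1), nAgeProbes, replace = TRUE) *
    slopeScale * runif(nAgeProbes, 0.5, 1.5)
  midLevel <- runif(nAgeProbes, 0.15, 0.85)
  icpt <- stats::qlogis(midLevel) - slope * mean(ageRange)
  tissueLv <- unique(tissue)
  tissueOffset <- matrix(rnorm(nAgeProbes * length(tissueLv),
                               sd = tissueEffectSd),
                         nAgeProbes, length(tissueLv),
                         dimnames = list(NULL, tissueLv))
  noiseLevel <- runif(nProbes - nAgeProbes, 0.05, 0.95)

  mu <- matrix(0, nProbes, nSamples)
  if (nAgeProbes > 0L)
    mu[ageProbeIdx, ] <- stats::plogis(
      outer(icpt, rep(1, nSamples)) + outer(slope, age) +
        tissueOffset[, tissue, drop = FALSE])
  noiseIdx <- setdiff(seq_len(nProbes), ageProbeIdx)
  if (length(noiseIdx)) mu[noiseIdx, ] <- noiseLevel
  if (repSd > 0) {
    repIdx <- which(!is.na(replicateOf))
    wobble <- rnorm(length(repIdx), sd = repSd)
    mu[, repIdx] <- stats::plogis(stats::qlogis(mu[, repIdx, drop = FALSE]) +
                                    rep(wobble, each = nProbes))
  }

  eps <- 1e-6
  mu <- pmin(pmax(mu, eps), 1 - eps)
  beta <- matrix(rbeta(nProbes * nSamples, mu * kappa, (1 - mu) * kappa),
                 nProbes, nSamples,
                 dimnames = list(probeIds, sampleIds))
  beta <- pmin(pmax(beta, eps), 1 - eps)
  if (missingRate > 0)
    beta[runif(length(beta)) < missingRate] <- NA_real_

  samples <- data.frame(
    sample_id = sampleIds, age = age,
    sex = sample(c("F", "M"), nSamples, replace = TRUE),
    tissue = tissue,
    sun_exposure = sample(c("exposed", "protected"), nSamples,
                          replace = TRUE),
    dataset = "synthetic", group = group, stringsAsFactors = FALSE)
  manifest <- data.frame(
    probe_id = probeIds,
    chromosome = sample(paste0("chr", 1:22), nProbes, replace = TRUE),
    position = sample.int(2^28, nProbes),
    gene = sprintf("GENE%04d", rep_len(seq_len(max(1L, nProbes %/% 2L)),
                                       nProbes)),
    region = sample(setdiff(REGION_LEVELS, "intergenic"), nProbes,
                    replace = TRUE),
    cross_reactive = FALSE, on_target_platform = TRUE,
    stringsAsFactors = FALSE)
  truth <- list(
    age_probes = data.frame(probe_id = probeIds[ageProbeIdx],
                            intercept = icpt, slope = slope,
                            stringsAsFactors = FALSE),
    age = stats::setNames(age, sampleIds),
    tissue = stats::setNames(tissue, sampleIds),
    replicate_of = stats::setNames(replicateOf, sampleIds))
  list(beta = beta, samples = samples, manifest = manifest, truth = truth)
}

#' Build a probe manifest with exact filter-accounting counts
#'
#' Constructs a manifest whose sequential filter arithmetic is fully
#' controlled: `nCrossReactive` probes flagged cross-reactive,
#' `nOffPlatform` further (disjoint) probes flagged off-platform, and the
#' rest clean. When `sexSubsetOfFlagged` is `TRUE` (the situation in which
#' the sex-chromosome step removes nothing extra) all chrX/chrY assignments
#' are placed inside already-flagged records; otherwise `nSexExtra`
#' unflagged probes are put on chrY and are removed by the third step.
#'
#' @param nTotal total probes.
#' @param nCrossReactive,nOffPlatform disjoint flag counts; their sum must
#'   not exceed `nTotal`.
#' @param sexSubsetOfFlagged logical (default `TRUE`).
#' @param nSexExtra unflagged sex-chromosome probes (only used when
#'   `sexSubsetOfFlagged` is `FALSE`).
#' @return a probe manifest data.frame.
#' @export
makeFilterFixture <- function(nTotal, nCrossReactive, nOffPlatform,
                              sexSubsetOfFlagged = TRUE, nSexExtra = 0L) {
  if (nCrossReactive + nOffPlatform > nTotal)
    stop("inconsistent counts: flagged probes exceed total", call. = FALSE)
  if (!sexSubsetOfFlagged &&
      nCrossReactive + nOffPlatform + nSexExtra > nTotal)
    stop("inconsistent counts: flagged + sex probes exceed total",
         call. = FALSE)
  probeIds <- sprintf("cgF%07d", seq_len(nTotal))
  cross <- seq_len(nCrossReactive)
  off <- seq_len(nOffPlatform) + nCrossReactive
  chrom <- rep("chr1", nTotal)
  if (sexSubsetOfFlagged) {
    flagged <- c(cross, off)
    if (length(flagged)) chrom[flagged[seq_len(min(2L, length(flagged)))]] <-
        c("chrX", "chrY")[seq_len(min(2L, length(flagged)))]
  } else if (nSexExtra > 0L) {
    chrom[nCrossReactive + nOffPlatform + seq_len(nSexExtra)] <- "chrY"
  }
  data.frame(
    probe_id = probeIds, chromosome = chrom, position = seq_len(nTotal),
    gene = "", region = "Body",
    cross_reactive = seq_len(nTotal) %in% cross,
    on_target_platform = !(seq_len(nTotal) %in% off),
    stringsAsFactors = FALSE)
}
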