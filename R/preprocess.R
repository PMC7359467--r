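## Quantile normalization of beta values and sequential probe filtering.

#' Quantile-normalize a beta matrix across samples
#'
#' Forces every sample's value distribution onto a common reference — the
#' arithmetic mean of the per-sample sorted value vectors — while preserving
#' each sample's internal ranking, the standard pre-processing step before
#' fitting methylation clocks across array batches. Tied values within a
#' sample receive the mean of the reference values their rank span covers
#' (average-rank convention), which makes the map idempotent.
#'
#' @param m numeric beta matrix (probes x samples), no missing values; run
#'   [dropMissingProbes()] first.
#' @return the normalized matrix: every column is a permutation of the
#'   reference distribution (up to tie-averaging) and values stay in
#'   `[0, 1]`.
#' @examples
#' m <- cbind(s1 = c(0.1, 0.2, 0.3), s2 = c(0.3, 0.5, 0.7))
#' rownames(m) <- paste0("cg", 1:3)
#' quantileNormalizeBetas(m)  # both columns become (0.2, 0.35, 0.5)
#' @export
quantileNormalizeBetas <- function(m) {
  validateBetaMatrix(m)
  if (anyNA(m))
    stop("missing values present; run dropMissingProbes() first",
         call. = FALSE)
  if (ncol(m) == 1L) {
    warning("single sample: quantile normalization is a no-op",
            call. = FALSE)
    return(m)
  }
  ref <- rowMeans(apply(m, 2L, sort.int, method = "quick"))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    xs <- x[o]
    grp <- cumsum(c(TRUE, xs[-1L] != xs[-length(xs)]))
    out[o, j] <- stats::ave(ref, grp)
  }
  out
}

#' Drop probes with missing beta values
#'
#' @param m beta matrix, missing values allowed.
#' @return list with `matrix` (probes with zero missing entries, original
#'   order) and `removed` (count of dropped probes).
#' @export
dropMissingProbes <- function(m) {
  validateBetaMatrix(m)
  keep <- rowSums(is.na(m)) == 0L
  if (!any(keep))
    stop("every probe has at least one missing value", call. = FALSE)
  list(matrix = m[keep, , drop = FALSE], removed = sum(!keep))
}

#' Apply the standard probe filters with full accounting
#'
#' Removes, in fixed order: (1) probes with missing values, (2)
#' cross-reactive probes, (3) probes absent from the target platform
#' (`on_target_platform == FALSE`), (4) sex-chromosome probes (chrX/chrY).
#' Each removal count is relative to the probes remaining after the previous
#' step, so the [FilterReport-class] arithmetic is exactly reproducible.
#' Surviving probes keep their input order.
#'
#' @param m beta matrix.
#' @param manifest probe manifest covering the probes of `m` (unlisted
#'   probes are treated as autosomal and unflagged, matching
#'   [assembleDataset()]'s fallback).
#' @return list with `matrix` (survivors) and `report`
#'   ([FilterReport-class]).
#' @export
filterProbes <- function(m, manifest) {
  validateBetaMatrix(m)
  validateProbeManifest(manifest)
  nInput <- nrow(m)

  dm <- if (anyNA(m)) dropMissingProbes(m) else list(matrix = m, removed = 0L)
  m <- dm$matrix

  unlisted <- setdiff(rownames(m), manifest$probe_id)
  if (length(unlisted))
    manifest <- rbind(manifest[, MANIFEST_COLUMNS],
                      .fallbackManifestRows(unlisted))
  ann <- manifest[match(rownames(m), manifest$probe_id), , drop = FALSE]

  crossReactive <- ann$cross_reactive %in% TRUE
  nCross <- sum(crossReactive)
  m <- m[!crossReactive, , drop = FALSE]
  ann <- ann[!crossReactive, , drop = FALSE]

  offPlatform <- !(ann$on_target_platform %in% TRUE)
  nOff <- sum(offPlatform)
  m <- m[!offPlatform, , drop = FALSE]
  ann <- ann[!offPlatform, , drop = FALSE]

  sexChrom <- ann$chromosome %in% c("chrX", "chrY")
  nSex <- sum(sexChrom)
  m <- m[!sexChrom, , drop = FALSE]

  if (nrow(m) == 0L)
    stop("no probes survive filtering", call. = FALSE)
  report <- FilterReport(nInput, dm$removed, nCross, nOff, nSex, nrow(m))
  validObject(report)
  list(matrix = m, report = report)
}
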