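## Tabular artifacts: beta matrix, sample table, probe manifest (all TSV,
## UTF-8, NA token "NA") and clock models (single JSON document).

REGION_LEVELS <- c("TSS200", "TSS1500", "5UTR", "1stExon", "Body", "3UTR",
                   "intergenic")
CHROM_LEVELS <- c(paste0("chr", 1:22), "chrX", "chrY", "unknown")
SEX_LEVELS <- c("F", "M", "unknown")
TISSUE_LEVELS <- c("dermis", "epidermis", "whole_skin", "other")
SUN_LEVELS <- c("exposed", "protected", "unknown")
SAMPLE_COLUMNS <- c("sample_id", "age", "sex", "tissue", "sun_exposure",
                    "dataset", "group")
MANIFEST_COLUMNS <- c("probe_id", "chromosome", "position", "gene", "region",
                      "cross_reactive", "on_target_platform")

.assertUnique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, ": ", paste(head(dup, 5), collapse = ", "),
         if (length(dup) > 5) " ..." else "", call. = FALSE)
}

#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions with probes as
#' rows (unique rownames) and samples as columns (unique colnames); every
#' non-missing value must lie in `[0, 1]`.
#'
#' @param m numeric matrix, probes x samples.
#' @param allowMissing logical; permit `NA` entries (the pre-normalization
#'   state).
#' @return `m`, invisibly, after validation.
#' @export
validateBetaMatrix <- function(m, allowMissing = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  if (ncol(m) == 0L) stop("beta matrix has no sample columns", call. = FALSE)
  if (nrow(m) == 0L) stop("beta matrix has no probes", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("beta matrix needs probe rownames and sample colnames",
         call. = FALSE)
  .assertUnique(rownames(m), "probe ids")
  .assertUnique(colnames(m), "sample ids")
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, ]
    stop(sprintf(
      "beta value %.4g outside [0,1] at probe '%s', sample '%s' (%d offending values)",
      m[i[1L], i[2L]], rownames(m)[i[1L]], colnames(m)[i[2L]], nrow(bad)),
      call. = FALSE)
  }
  if (!allowMissing && anyNA(m))
    stop("beta matrix contains missing values", call. = FALSE)
  invisible(m)
}

#' Read or write a beta-value matrix TSV
#'
#' The on-disk dialect is tab-separated UTF-8 with a first column `probe_id`,
#' a header row of sample ids, and "NA" as the missing-value token.
#'
#' @param path file path.
#' @return `readBetaMatrix`: a validated numeric matrix (probes x samples).
#' @export
readBetaMatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L)
    stop("beta matrix file has no sample columns: ", path, call. = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dt[[1L]]
  validateBetaMatrix(m)
  m
}

#' @rdname readBetaMatrix
#' @param m numeric beta matrix, probes x samples.
#' @export
writeBetaMatrix <- function(m, path) {
  validateBetaMatrix(m)
  dt <- data.table::data.table(probe_id = rownames(m), m)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.checkVocab <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(head(bad, 5), collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")", call. = FALSE)
}

#' Validate a per-sample metadata table
#'
#' Required columns: `sample_id` (unique), `age` (years, >= 0 or NA),
#' `sex` (F/M/unknown), `tissue` (dermis/epidermis/whole_skin/other),
#' `sun_exposure` (exposed/protected/unknown), `dataset`, `group`.
#'
#' @param df data.frame.
#' @return `df`, invisibly, after validation.
#' @export
validateSampleTable <- function(df) {
  miss <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .assertUnique(df$sample_id, "sample ids")
  if (any(!is.na(df$age) & df$age < 0))
    stop("negative age for sample(s): ",
         paste(df$sample_id[!is.na(df$age) & df$age < 0], collapse = ", "),
         call. = FALSE)
  .checkVocab(df$sex, SEX_LEVELS, "sex")
  .checkVocab(df$tissue, TISSUE_LEVELS, "tissue")
  .checkVocab(df$sun_exposure, SUN_LEVELS, "sun_exposure")
  invisible(df)
}

#' Read or write a sample metadata TSV
#' @param path file path.
#' @return `readSampleTable`: a validated data.frame.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE,
                          colClasses = list(character = "sample_id"))
  df$age <- as.numeric(df$age)
  validateSampleTable(df)
  df
}

#' @rdname readSampleTable
#' @param df sample table data.frame.
#' @export
writeSampleTable <- function(df, path) {
  validateSampleTable(df)
  data.table::fwrite(df[, SAMPLE_COLUMNS], path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Validate a probe annotation manifest
#'
#' Required columns: `probe_id` (unique), `chromosome` (chr1..chr22, chrX,
#' chrY, unknown), `position` (1-based, >= 1 or NA), `gene` (zero or more
#' `;`-separated symbols), `region` (TSS200/TSS1500/5UTR/1stExon/Body/3UTR/
#' intergenic), `cross_reactive` and `on_target_platform` (logical).
#'
#' @param df data.frame.
#' @return `df`, invisibly, after validation.
#' @export
validateProbeManifest <- function(df) {
  miss <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(miss))
    stop("probe manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .assertUnique(df$probe_id, "probe ids")
  .checkVocab(df$chromosome, CHROM_LEVELS, "chromosome")
  .checkVocab(df$region, REGION_LEVELS, "region")
  if (any(!is.na(df$position) & df$position < 1))
    stop("manifest position < 1 for probe(s): ",
         paste(df$probe_id[!is.na(df$position) & df$position < 1],
               collapse = ", "), call. = FALSE)
  if (!is.logical(df$cross_reactive) || !is.logical(df$on_target_platform))
    stop("cross_reactive and on_target_platform must be logical",
         call. = FALSE)
  invisible(df)
}

#' Read or write a probe manifest TSV
#' @param path file path.
#' @return `readProbeManifest`: a validated data.frame.
#' @export
readProbeManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE,
                          colClasses = list(character = c("probe_id"),
                                            logical = c("cross_reactive",
                                                        "on_target_platform")))
  df$gene <- as.character(df$gene)
  df$gene[is.na(df$gene)] <- ""
  validateProbeManifest(df)
  df
}

#' @rdname readProbeManifest
#' @param df probe manifest data.frame.
#' @export
writeProbeManifest <- function(df, path) {
  validateProbeManifest(df)
  data.table::fwrite(df[, MANIFEST_COLUMNS], path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

.fallbackManifestRows <- function(probeIds) {
  data.frame(probe_id = probeIds, chromosome = "unknown",
             position = NA_integer_, gene = "", region = "intergenic",
             cross_reactive = FALSE, on_target_platform = FALSE,
             stringsAsFactors = FALSE)
}

#' Load a methylation dataset as a SummarizedExperiment
#'
#' Reads the beta matrix, sample table and probe manifest, cross-validates
#' them, and assembles a [SummarizedExperiment::SummarizedExperiment] with
#' the beta values as assay `"beta"`, sample metadata as `colData` and probe
#' annotation as `rowData`. Every beta-matrix sample must appear in the
#' sample table; probes absent from the manifest are retained with
#' `region = "intergenic"` and all flags `FALSE`, with a warning.
#'
#' @param betaPath,samplesPath,manifestPath TSV file paths.
#' @return A `SummarizedExperiment`.
#' @examples
#' \dontrun{se <- loadDataset("beta.tsv", "samples.tsv", "manifest.tsv")}
#' @export
loadDataset <- function(betaPath, samplesPath, manifestPath) {
  beta <- readBetaMatrix(betaPath)
  samples <- readSampleTable(samplesPath)
  manifest <- readProbeManifest(manifestPath)
  assembleDataset(beta, samples, manifest)
}

#' @rdname loadDataset
#' @param beta beta matrix; `samples` sample table; `manifest` probe
#'   manifest (already in memory).
#' @param samples,manifest see above.
#' @export
assembleDataset <- function(beta, samples, manifest) {
  validateBetaMatrix(beta)
  validateSampleTable(samples)
  validateProbeManifest(manifest)
  missingSamples <- setdiff(colnames(beta), samples$sample_id)
  if (length(missingSamples))
    stop("beta-matrix sample(s) absent from sample table: ",
         paste(head(missingSamples, 5), collapse = ", "), call. = FALSE)
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  unannotated <- setdiff(rownames(beta), manifest$probe_id)
  if (length(unannotated)) {
    warning(length(unannotated),
            " probe(s) missing from manifest; kept as intergenic/unflagged",
            call. = FALSE)
    manifest <- rbind(manifest[, MANIFEST_COLUMNS],
                      .fallbackManifestRows(unannotated))
  }
  manifest <- manifest[match(rownames(beta), manifest$probe_id), ,
                       drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id),
    rowData = S4Vectors::DataFrame(manifest, row.names = manifest$probe_id))
}

#' Extract the beta assay / sample table / probe manifest from a dataset
#' @param se a `SummarizedExperiment` built by [loadDataset()].
#' @return a matrix (`betaValues`) or data.frame.
#' @export
betaValues <- function(se) SummarizedExperiment::assay(se, "beta")

#' @rdname betaValues
#' @export
sampleData <- function(se)
  as.data.frame(SummarizedExperiment::colData(se))

#' @rdname betaValues
#' @export
probeData <- function(se)
  as.data.frame(SummarizedExperiment::rowData(se))

#' Merge beta matrices from several datasets
#'
#' Probes are intersected (datasets are typically run on overlapping but not
#' identical probe sets); the output keeps the first matrix's probe order and
#' concatenates sample columns. Sample ids must be globally unique.
#'
#' @param matrices list of beta matrices.
#' @return a single merged beta matrix.
#' @export
mergeBetaMatrices <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need at least one matrix", call. = FALSE)
  lapply(matrices, validateBetaMatrix)
  allSamples <- unlist(lapply(matrices, colnames))
  .assertUnique(allSamples, "sample ids across datasets")
  if (length(matrices) == 1L) return(matrices[[1L]])
  probes <- rownames(matrices[[1L]])
  for (m in matrices[-1L]) probes <- probes[probes %in% rownames(m)]
  if (!length(probes))
    stop("empty probe intersection across datasets", call. = FALSE)
  do.call(cbind, lapply(matrices, function(m) m[probes, , drop = FALSE]))
}

#' Serialize / deserialize a ClockModel as JSON
#'
#' The clock is stored as one JSON document with fields `intercept`,
#' `weights`, `training_probe_means` and `provenance`, so a model version is
#' a single atomic file. Reading reproduces the coefficients to full stored
#' precision.
#'
#' @param model a [ClockModel-class].
#' @param path file path.
#' @export
writeClockModel <- function(model, path) {
  if (is(model, "NonlinearClock"))
    stop("non-linear clocks (random forest / SVM) are not serializable",
         call. = FALSE)
  validObject(model)
  doc <- list(intercept = model@intercept,
              weights = as.list(model@weights),
              training_probe_means = as.list(model@trainingMeans),
              provenance = model@provenance)
  # digits = I(17): shortest representation that round-trips IEEE doubles
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeClockModel
#' @return `readClockModel`: the deserialized [ClockModel-class].
#' @export
readClockModel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed clock file: ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("intercept", "weights", "training_probe_means")) {
    if (is.null(doc[[field]]))
      stop("clock file missing field '", field, "'", call. = FALSE)
  }
  if (!is.numeric(doc$intercept) || length(doc$intercept) != 1L)
    stop("clock field 'intercept' must be a single number", call. = FALSE)
  w <- unlist(doc$weights)
  if (!length(w) || !is.numeric(w) || is.null(names(w)))
    stop("clock field 'weights' must be a named numeric map", call. = FALSE)
  mu <- unlist(doc$training_probe_means)
  if (!is.numeric(mu) || is.null(names(mu)))
    stop("clock field 'training_probe_means' must be a named numeric map",
         call. = FALSE)
  prov <- doc$provenance
  if (is.null(prov)) prov <- list()
  prov$n_probes <- NULL
  ClockModel(doc$intercept, w, mu, prov)
}
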