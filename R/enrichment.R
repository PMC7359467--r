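## Over-representation analysis of clock-associated gene lists against
## user-supplied gene sets (GMT), with Bonferroni control by default.

#' Read gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then member gene symbols.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L)
      stop("GMT line needs name, description and >= 1 gene", call. = FALSE)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

#' Read a one-symbol-per-line gene list
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance when drawing `n = |list|` genes from a universe
#' of `N` genes containing `K` set members: the p-value is the upper-tail
#' hypergeometric probability `P(X >= k)` of seeing at least the observed
#' overlap `k`. The enrichment ratio is `(k/n) / (K/N)`. P-values are
#' Bonferroni-adjusted across sets by default (raw p times the number of
#' sets tested, capped at 1); Benjamini-Hochberg is available as an
#' alternative.
#'
#' @param geneList character, query gene symbols; symbols outside the
#'   universe are dropped with a warning.
#' @param geneSets named list of character vectors (e.g. from [readGMT()]);
#'   each set is intersected with the universe.
#' @param universe character, all assayable gene symbols.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return data.frame sorted by raw p-value, one row per set: `set_name`,
#'   `universe_size`, `set_size`, `list_size`, `overlap`,
#'   `enrichment_ratio`, `p_value`, `p_adjusted`, `overlap_genes`
#'   (`;`-separated).
#' @export
runORA <- function(geneList, geneSets, universe,
                   adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(geneList)) stop("empty gene list", call. = FALSE)
  if (!is.list(geneSets) || is.null(names(geneSets)) || !length(geneSets))
    stop("geneSets must be a non-empty named list", call. = FALSE)
  geneList <- unique(geneList)
  outside <- setdiff(geneList, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    geneList <- intersect(geneList, universe)
  }
  if (!length(geneList))
    stop("no query genes remain inside the universe", call. = FALSE)

  N <- length(universe)
  n <- length(geneList)
  nSets <- length(geneSets)
  res <- do.call(rbind, lapply(names(geneSets), function(nm) {
    members <- intersect(unique(geneSets[[nm]]), universe)
    K <- length(members)
    hits <- sort(intersect(geneList, members))
    k <- length(hits)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, universe_size = N, set_size = K,
               list_size = n, overlap = k,
               enrichment_ratio = if (K > 0) (k / n) / (K / N) else NA_real_,
               p_value = p,
               overlap_genes = paste(hits, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- if (adjust == "bonferroni")
    pmin(1, res$p_value * nSets) else p.adjust(res$p_value, "BH")
  res <- res[order(res$p_value, res$set_name),
             c("set_name", "universe_size", "set_size", "list_size",
               "overlap", "enrichment_ratio", "p_value", "p_adjusted",
               "overlap_genes")]
  rownames(res) <- NULL
  res
}
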