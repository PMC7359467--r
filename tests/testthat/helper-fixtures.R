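# Fixtures are built in code: small matrices, tables and TSV triples.

toyBeta <- function(values, nProbe, nSample,
                    probes = sprintf("cg%03d", seq_len(nProbe)),
                    samples = sprintf("s%02d", seq_len(nSample))) {
  matrix(values, nProbe, nSample, dimnames = list(probes, samples))
}

toySamples <- function(ids, age = seq(20, by = 5, length.out = length(ids)),
                       tissue = "epidermis", group = "none",
                       dataset = "toy") {
  data.frame(sample_id = ids, age = age, sex = "F",
             tissue = rep_len(tissue, length(ids)),
             sun_exposure = "unknown", dataset = dataset,
             group = rep_len(group, length(ids)),
             stringsAsFactors = FALSE)
}

toyManifest <- function(probes, chromosome = "chr1", region = "Body",
                        crossReactive = FALSE, onTarget = TRUE) {
  data.frame(probe_id = probes,
             chromosome = rep_len(chromosome, length(probes)),
             position = seq_along(probes), gene = "",
             region = rep_len(region, length(probes)),
             cross_reactive = rep_len(crossReactive, length(probes)),
             on_target_platform = rep_len(onTarget, length(probes)),
             stringsAsFactors = FALSE)
}

# write a (beta, samples, manifest) triple to TSVs; returns the paths
writeTriple <- function(beta, samples, manifest, dir = withr::local_tempdir(
                          .local_envir = parent.frame())) {
  paths <- list(beta = file.path(dir, "beta.tsv"),
                samples = file.path(dir, "samples.tsv"),
                manifest = file.path(dir, "manifest.tsv"))
  writeBetaMatrix(beta, paths$beta)
  writeSampleTable(samples, paths$samples)
  writeProbeManifest(manifest, paths$manifest)
  paths
}

# exact Pearson r via the textbook sum formula (oracle independent of cor())
pearsonByHand <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}
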