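#' Build the genotype-by-replicate sample design
#'
#' @param config A [simulation_config()] (only `n_replicates` is used).
#' @param genotypes Genotype labels; the first is the parental reference.
#' @return A `data.frame` with columns `sample`, `genotype`, `replicate`,
#'   `included`.
#' @export
make_design <- function(config = simulation_config(),
                        genotypes = c("WT", "sigW", "rasP", "prsW")) {
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        genotype = genotypes, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "replicate")]
  design$sample <- paste(design$genotype, design$replicate, sep = "_")
  design$included <- TRUE
  rownames(design) <- NULL
  design[, c("sample", "genotype", "replicate", "included")]
}

#' Simulate strand-specific probe-level tiling signals
#'
#' Tiles probes every `probe_step` bases on both strands and fills one
#' log2-scale signal column per sample. For a probe lying entirely within a
#' feature on the same strand the expected signal is the feature's planted
#' baseline plus the genotype effect; probes outside all features measure a
#' background level. Gaussian noise, a per-array monotone distortion and a
#' configurable fraction of corrupted non-unique probes are layered on top.
#' With `outlier_array = TRUE` the last prsW replicate is replaced by a
#' profile drawn from an unrelated baseline (a stationary-phase-like
#' hybridization), the scenario [flag_outlier_arrays()] must catch.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [generate_truth()].
#' @param design A design table as from [make_design()].
#' @param config The [simulation_config()].
#' @return A `data.frame` of class `"probe_signal_set"`: `probe`, `start`,
#'   `end`, `strand`, `unique_match`, then one numeric column per sample.
#' @export
simulate_probe_signals <- function(annotation, truth, design, config) {
  validate_config(config)
  validate_annotation(annotation)
  known <- c("WT", "sigW", "rasP", "prsW")
  if (!all(design$genotype %in% known))
    stop("sample design references unknown genotype(s): ",
         paste(setdiff(design$genotype, known), collapse = ", "))
  set.seed(config$seed + 3L)

  starts <- seq.int(1L, config$genome_length - config$probe_length + 1L,
                    by = config$probe_step)
  probes <- data.frame(
    probe = c(sprintf("pf%06d", seq_along(starts)),
              sprintf("pr%06d", seq_along(starts))),
    start = rep(starts, 2L),
    end = rep(starts + config$probe_length - 1L, 2L),
    strand = rep(c("+", "-"), each = length(starts)),
    stringsAsFactors = FALSE)
  probes$unique_match <- runif(nrow(probes)) >= config$nonunique_fraction

  feat_of <- match_probes_to_features(probes, annotation)
  fidx <- match(feat_of, truth$feature)

  background_level <- 4
  base <- ifelse(is.na(fidx), background_level, truth$baseline[fidx])
  eff <- cbind(WT = 0,
               sigW = ifelse(is.na(fidx), 0, truth$effect_sigW[fidx]),
               rasP = ifelse(is.na(fidx), 0, truth$effect_rasP[fidx]),
               prsW = ifelse(is.na(fidx), 0, truth$effect_prsW[fidx]))

  outlier_sample <- NA_character_
  if (config$outlier_array) {
    prs <- design$sample[design$genotype == "prsW"]
    if (length(prs)) outlier_sample <- prs[length(prs)]
    alt_baseline <- runif(nrow(truth), 6, 10)
    alt <- ifelse(is.na(fidx), background_level, alt_baseline[fidx])
  }

  distortions <- runif(nrow(design), -config$array_distortion,
                       config$array_distortion)
  for (s in seq_len(nrow(design))) {
    mu <- base + eff[, design$genotype[s]]
    if (identical(design$sample[s], outlier_sample)) mu <- alt
    y <- mu + rnorm(nrow(probes), 0, config$noise_sd)
    # corrupted signal on non-unique probes (cross-hybridization)
    nbad <- sum(!probes$unique_match)
    if (nbad) y[!probes$unique_match] <- y[!probes$unique_match] +
        1.5 + rnorm(nbad, 0, 0.5)
    # monotone per-array distortion: y + d * sigmoid(y - 7), strictly
    # increasing for |d| < 2
    if (config$array_distortion > 0)
      y <- y + distortions[s] * stats::plogis(y - 7) * 2
    probes[[design$sample[s]]] <- y
  }
  attr(probes, "outlier_sample") <- outlier_sample
  class(probes) <- c("probe_signal_set", "data.frame")
  probes
}

# same-strand "probe entirely within feature" assignment; NA outside features
match_probes_to_features <- function(probes, annotation) {
  pg <- GenomicRanges::GRanges("chr", IRanges::IRanges(probes$start, probes$end),
                               strand = probes$strand)
  fg <- annotation_granges(annotation)
  hits <- GenomicRanges::findOverlaps(pg, fg, type = "within", ignore.strand = FALSE)
  out <- rep(NA_character_, nrow(probes))
  out[S4Vectors::queryHits(hits)] <-
    annotation$feature[S4Vectors::subjectHits(hits)]
  out
}

#' Simulate an aggregated feature-by-sample expression matrix directly
#'
#' A light-weight generator used for statistical calibration at large feature
#' counts: it skips the probe layer and draws each aggregated log2 value as
#' baseline + genotype effect + Gaussian noise. This matches the model the
#' per-feature fit assumes and is the appropriate input for type-I error,
#' FDR and effect-recovery studies with thousands of features.
#'
#' @param effects A data.frame or list with per-feature effect vectors named
#'   after non-reference genotypes (e.g. `sigW`, `rasP`, `prsW`); missing
#'   genotypes get effect 0.
#' @param design A design table as from [make_design()].
#' @param noise_sd Gaussian noise standard deviation (log2 scale).
#' @param baseline Scalar or per-feature baseline log2 expression.
#' @param seed Optional seed set before drawing.
#' @return A numeric matrix, features x samples.
#' @export
simulate_feature_matrix <- function(effects, design, noise_sd = 0.25,
                                    baseline = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  effects <- as.list(effects)
  n <- length(effects[[1]])
  stopifnot(all(vapply(effects, length, 1L) == n))
  mat <- matrix(0, n, nrow(design),
                dimnames = list(sprintf("f%05d", seq_len(n)), design$sample))
  for (s in seq_len(nrow(design))) {
    g <- design$genotype[s]
    eff <- if (g %in% names(effects)) effects[[g]] else 0
    mat[, s] <- baseline + eff + rnorm(n, 0, noise_sd)
  }
  mat
}
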