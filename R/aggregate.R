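#' Running-median smoothing of probe signals
#'
#' Replaces each probe's signal by the median over a window of `window`
#' probes centred on it, computed per strand along genomic order. Windows
#' are truncated at the ends of each strand (the first probe's window is the
#' first `(window + 1) / 2` probes, and so on), so the probe set and
#' coordinates are unchanged and no signal is invented beyond the data.
#' Interior positions use [stats::runmed()] (Turlach algorithm); the
#' truncated end windows are computed explicitly.
#'
#' @param probes A `probe_signal_set` (see [simulate_probe_signals()]).
#' @param window Odd window size in probes; `1` is the identity.
#' @return The probe set with every sample column smoothed.
#' @export
smooth_signal <- function(probes, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1")
  sample_cols <- probe_sample_cols(probes)
  if (window == 1L) return(probes)
  ord <- order(probes$strand, probes$start)
  out <- probes
  for (str in unique(probes$strand)) {
    idx <- ord[probes$strand[ord] == str]
    for (col in sample_cols)
      out[[col]][idx] <- running_median(probes[[col]][idx], window)
  }
  out
}

# sliding median with truncated (not padded) end windows
running_median <- function(x, window) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  if (n <= window) {
    return(vapply(seq_len(n), function(i)
      median(x[max(1L, i - half):min(n, i + half)]), numeric(1)))
  }
  y <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  for (i in seq_len(half)) {
    y[i] <- median(x[1L:(i + half)])
    y[n - i + 1L] <- median(x[(n - i + 1L - half):n])
  }
  y
}

probe_sample_cols <- function(probes) {
  meta <- c("probe", "start", "end", "strand", "unique_match")
  missing <- setdiff(meta, names(probes))
  if (length(missing))
    stop("probe table lacks required columns: ", paste(missing, collapse = ", "))
  setdiff(names(probes), meta)
}

#' Aggregate probe signals into per-feature expression values
#'
#' For each annotated feature and each sample, the aggregated log2 expression
#' is the median of the (smoothed) signals of probes that (i) match the
#' genome uniquely, (ii) lie on the same strand as the feature and (iii) lie
#' entirely within the feature boundaries (probe start >= feature start and
#' probe end <= feature end; 1-based closed coordinates). Features with no
#' eligible probe are reported and masked `NA` rather than zero-filled — a
#' zero would masquerade as a measurement. Masking is by construction
#' identical across samples.
#'
#' @param probes A (smoothed) `probe_signal_set`.
#' @param annotation A `genome_annotation`.
#' @return A numeric matrix, features x samples, with attribute `"masked"`
#'   listing features that had no eligible probes.
#' @export
aggregate_features <- function(probes, annotation) {
  validate_annotation(annotation)
  if (!all(probes$strand %in% c("+", "-")))
    stop("probe strand vocabulary must be '+'/'-' to match the annotation")
  sample_cols <- probe_sample_cols(probes)
  keep <- probes$unique_match
  feat_of <- match_probes_to_features(probes[keep, , drop = FALSE], annotation)
  groups <- split(which(keep), factor(feat_of, levels = annotation$feature))[
    annotation$feature]
  mat <- matrix(NA_real_, nrow(annotation), length(sample_cols),
                dimnames = list(annotation$feature, sample_cols))
  for (col in sample_cols) {
    x <- probes[[col]]
    mat[, col] <- vapply(groups, function(ix)
      if (length(ix)) median(x[ix]) else NA_real_, numeric(1))
  }
  masked <- annotation$feature[vapply(groups, length, 1L) == 0L]
  if (length(masked))
    message(length(masked), " feature(s) had no eligible probes and were masked")
  attr(mat, "masked") <- masked
  mat
}
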