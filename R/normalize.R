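#' Quantile normalization of an expression matrix
#'
#' Forces every sample column to share the same value multiset — the
#' across-sample mean of order statistics — while preserving within-column
#' ranks, removing monotone technical trends between hybridizations. Ties
#' are broken by stable input order when ranks are assigned (no average-rank
#' substitution), which makes the transform exactly idempotent.
#'
#' @param expr Numeric matrix, features x samples, with no missing values
#'   (drop masked features first).
#' @return The normalized matrix; all columns have identical sorted values.
#' @export
quantile_normalize <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L || ncol(expr) == 0L)
    stop("cannot quantile-normalize an empty matrix")
  if (anyNA(expr))
    stop("expression matrix contains missing values; drop masked features first")
  ords <- apply(expr, 2L, order)               # stable order: ties keep input order
  sorted <- vapply(seq_len(ncol(expr)),
                   function(j) expr[ords[, j], j], numeric(nrow(expr)))
  target <- rowMeans(sorted)
  out <- expr
  for (j in seq_len(ncol(expr))) out[ords[, j], j] <- target
  out
}

#' Flag atypical hybridizations
#'
#' Marks a sample as excluded when the Pearson correlation between its
#' expression profile and the per-feature median profile of all other
#' included samples falls below `min_correlation`. This catches arrays whose
#' transcriptome resembles a different physiological state altogether (the
#' baseline-swap scenario of the simulator) rather than mere noise. The
#' function refuses (with a warning, not an error) to auto-exclude an array
#' when that would leave fewer than two included replicates of its genotype,
#' unless `force = TRUE`.
#'
#' @param expr Numeric matrix, features x samples (columns named as in
#'   `design$sample`). Masked features (any `NA`) are ignored row-wise.
#' @param design Design table with columns `sample`, `genotype`, `included`.
#' @param min_correlation Exclusion threshold on the correlation (default
#'   0.8).
#' @param force Override the minimum-replicate guard.
#' @return The design with `included` updated; attribute `"outlier_log"`
#'   holds a data.frame with each sample's correlation and decision.
#' @export
flag_outlier_arrays <- function(expr, design, min_correlation = 0.8,
                                force = FALSE) {
  expr <- as.matrix(expr)
  inc <- which(design$included)
  if (length(inc) < 3L) stop("need at least 3 included samples")
  expr <- expr[stats::complete.cases(expr), , drop = FALSE]
  cors <- rep(NA_real_, nrow(design))
  for (s in inc) {
    others <- expr[, design$sample[setdiff(inc, s)], drop = FALSE]
    ref <- apply(others, 1L, median)
    cors[s] <- cor(expr[, design$sample[s]], ref)
  }
  flagged <- !is.na(cors) & cors < min_correlation
  excluded <- flagged
  for (s in which(flagged)) {
    g <- design$genotype[s]
    left <- sum(design$included & design$genotype == g) - 1L
    if (left < 2L && !force) {
      warning(sprintf(paste0("sample %s (r = %.3f) is atypical but excluding it ",
                             "would leave %d replicate(s) of genotype %s; ",
                             "not auto-excluded (use force = TRUE)"),
                      design$sample[s], cors[s], left, g))
      excluded[s] <- FALSE
    }
  }
  out <- design
  out$included <- design$included & !excluded
  log <- data.frame(sample = design$sample, correlation = cors,
                    flagged = flagged, excluded = excluded,
                    stringsAsFactors = FALSE)
  if (any(excluded))
    message("excluded array(s): ",
            paste(sprintf("%s (r = %.3f)", design$sample[excluded],
                          cors[excluded]), collapse = ", "))
  attr(out, "outlier_log") <- log
  out
}
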