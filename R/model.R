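#' Per-feature one-factor genotype model
#'
#' Fits, for every feature, a single linear model of log2 expression on
#' genotype over the included samples, with one pooled residual variance per
#' feature across all genotypes. For a contrast `B/A` the effect value is the
#' fitted mean of genotype B minus the fitted mean of genotype A (equal to
#' the difference of sample means in the one-factor case), the standard
#' error comes from the pooled variance, and the two-sided p-value from the
#' t distribution with `n_included - n_genotypes` residual degrees of
#' freedom. Features with zero residual variance get a masked p-value and a
#' diagnostic flag rather than a fabricated 0 or 1, so they can be excluded
#' from FDR estimation.
#'
#' @param expr Numeric matrix, features x samples, quantile-normalized.
#' @param design Design table (`sample`, `genotype`, `included`).
#' @param contrasts Character vector of `"B/A"` contrast names; each genotype
#'   named must be present with at least two included replicates.
#' @return A `data.frame` of class `"contrast_table"` with columns `feature`,
#'   `contrast`, `effect`, `se`, `t`, `df`, `p`, `zero_variance`.
#' @examples
#' design <- make_design(simulation_config(n_replicates = 3))
#' expr <- simulate_feature_matrix(list(sigW = c(-2, 0)), design, seed = 1)
#' fit_genotype_model(expr, design, "sigW/WT")
#' @export
fit_genotype_model <- function(expr, design,
                               contrasts = c("sigW/WT", "rasP/WT", "prsW/WT",
                                             "rasP/sigW", "prsW/sigW")) {
  expr <- as.matrix(expr)
  design <- design[design$included, , drop = FALSE]
  expr <- expr[, design$sample, drop = FALSE]
  genos <- unique(design$genotype)
  parts <- strsplit(contrasts, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("contrasts must be of the form 'B/A'")
  named <- unique(unlist(parts))
  if (!all(named %in% genos))
    stop("contrast names absent genotype(s): ",
         paste(setdiff(named, genos), collapse = ", "))
  counts <- table(design$genotype)[named]
  if (any(counts < 2L))
    stop("need >= 2 included replicates for genotype(s): ",
         paste(named[counts < 2L], collapse = ", "))

  g <- factor(design$genotype, levels = genos)
  n_by_g <- as.vector(table(g))
  means <- t(rowsum(t(expr), g)) / rep(n_by_g, each = nrow(expr))
  colnames(means) <- levels(g)
  fitted <- means[, as.character(g), drop = FALSE]
  rss <- rowSums((expr - fitted)^2)
  df <- ncol(expr) - length(genos)
  if (df < 1L) stop("no residual degrees of freedom (need replicates)")
  s2 <- rss / df
  zero_var <- s2 <= .Machine$double.eps * 100

  out <- vector("list", length(contrasts))
  for (k in seq_along(contrasts)) {
    b <- parts[[k]][1]; a <- parts[[k]][2]
    effect <- means[, b] - means[, a]
    se <- sqrt(s2 * (1 / sum(g == b) + 1 / sum(g == a)))
    tval <- ifelse(zero_var, NA_real_, effect / se)
    pval <- ifelse(zero_var, NA_real_, 2 * pt(-abs(effect / se), df))
    out[[k]] <- data.frame(feature = rownames(expr), contrast = contrasts[k],
                           effect = unname(effect), se = unname(se),
                           t = unname(tval), df = df, p = unname(pval),
                           zero_variance = unname(zero_var),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "genotype_means") <- means
  class(res) <- c("contrast_table", "data.frame")
  res
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("Contrast table: %d features x %d contrast(s) [df = %d]\n",
              length(unique(x$feature)), length(unique(x$contrast)),
              x$df[1]))
  if (any(x$zero_variance))
    cat(sprintf("  %d feature-contrast rows masked (zero residual variance)\n",
                sum(x$zero_variance)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
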