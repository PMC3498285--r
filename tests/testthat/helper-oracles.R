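# Independently coded brute-force references. These deliberately use naive
# loops (or an unrelated library route) so they share no code path with the
# package implementations they check.

# quantile normalization: explicit rank/target loops
bf_quantile_normalize <- function(mat) {
  n <- nrow(mat)
  target <- numeric(n)
  for (k in seq_len(n)) {
    vals <- numeric(ncol(mat))
    for (j in seq_len(ncol(mat))) vals[j] <- sort(mat[, j])[k]
    target[k] <- mean(vals)
  }
  out <- mat
  for (j in seq_len(ncol(mat))) {
    ord <- order(mat[, j])          # stable: ties keep input order
    for (k in seq_len(n)) out[ord[k], j] <- target[k]
  }
  out
}

# sliding median with truncated end windows
bf_running_median <- function(x, window) {
  half <- (window - 1) %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- median(x[lo:hi])
  }
  out
}

# per-feature aggregation by explicit filtering
bf_aggregate <- function(probes, annotation, sample_col) {
  out <- setNames(rep(NA_real_, nrow(annotation)), annotation$feature)
  for (i in seq_len(nrow(annotation))) {
    sel <- probes$unique_match &
      probes$strand == annotation$strand[i] &
      probes$start >= annotation$start[i] &
      probes$end <= annotation$end[i]
    if (any(sel)) out[i] <- median(probes[[sample_col]][sel])
  }
  out
}

# one-factor fit through stats::lm, one feature at a time
bf_lm_contrast <- function(y, design, b, a) {
  d <- design[design$included, ]
  fit <- stats::lm(y ~ 0 + genotype, data = data.frame(y = y, genotype = d$genotype))
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  nb <- paste0("genotype", b); na_ <- paste0("genotype", a)
  effect <- cf[[nb]] - cf[[na_]]
  se <- sqrt(vc[nb, nb] + vc[na_, na_])
  tval <- effect / se
  list(effect = effect, se = se, t = tval, df = fit$df.residual,
       p = 2 * stats::pt(-abs(tval), fit$df.residual))
}

# adjusted Rand index from the pair-counting definition
bf_adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

small_config <- function(...) {
  simulation_config(n_operons = 12, genome_length = 60000, seed = 42, ...)
}
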