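#' Estimate the proportion of true null hypotheses (eta0)
#'
#' Empirical-null estimation from a p-value ensemble. The default
#' (`censored`) estimator counts p-values beyond a censoring point `p0` —
#' where the alternative contributes essentially nothing — and rescales:
#' `eta0 = #\{p > p0\} / (n (1 - p0))`. A Grenander-based smoother is
#' selectable instead: the decreasing Grenander density estimate of the
#' p-value distribution (slopes of the least concave majorant of the ECDF)
#' is averaged over `(p0, 1]`, where the alternative contributes essentially
#' nothing; the majorant irons out tail fluctuations of the raw count.
#' Both estimates are truncated
#' into `[1/n, 1]`; the floor prevents a degenerate zero when every p-value
#' is tiny.
#'
#' Ensembles smaller than 50 p-values carry too little information about the
#' null tail; the function then falls back to the conservative `eta0 = 1`
#' with a warning.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`; `NA`s (masked
#'   features) are ignored.
#' @param p0 Censoring point for the censored estimator (default 0.5).
#' @param method `"censored"` (default) or `"grenander"`.
#' @return The estimated null proportion, a scalar in `(0, 1]`.
#' @examples
#' set.seed(1)
#' estimate_eta0(runif(1000))            # near 1
#' estimate_eta0(c(runif(500), rbeta(500, 0.1, 1)))  # near 0.5
#' @export
estimate_eta0 <- function(pvalues, p0 = 0.5,
                          method = c("censored", "grenander")) {
  method <- match.arg(method)
  p <- pvalues[!is.na(pvalues)]
  if (length(p) && (min(p) < 0 || max(p) > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n < 50L) {
    warning("fewer than 50 p-values; falling back to eta0 = 1")
    return(1)
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  eta0 <- if (method == "censored") {
    sum(p > p0) / (n * (1 - p0))
  } else {
    grenander_eta0(p, p0)
  }
  min(max(eta0, 1 / n), 1)
}

# Grenander-smoothed censored estimator: the average of the decreasing
# Grenander density over (p0, 1], i.e. the mass the least concave majorant
# of the p-value ECDF leaves beyond the censoring point, rescaled. Smoother
# than the raw ECDF count because the majorant irons out tail fluctuations.
grenander_eta0 <- function(p, p0 = 0.5) {
  ps <- sort(p)
  n <- length(ps)
  x <- c(0, ps, 1)
  y <- c(0, seq_len(n) / n, 1)
  # least concave majorant via the upper hull (Andrew's monotone chain)
  hull <- integer(0)
  for (i in seq_along(x)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross >= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  lcm_at <- stats::approx(x[hull], y[hull], xout = p0, ties = "ordered")$y
  (1 - lcm_at) / (1 - p0)
}

#' Tail-area q-values from p-values and an eta0 estimate
#'
#' For p-values sorted ascending with rank `r` (ties sharing the largest
#' rank among them), the raw q-value is `eta0 * n * p / r`; monotonicity is
#' then enforced by a cumulative minimum from the largest p-value downward
#' and values are capped at 1. With `eta0 = 1` this is exactly the
#' Benjamini-Hochberg step-up adjustment. Masked (`NA`) p-values receive
#' masked q-values and do not count towards `n`.
#'
#' @param pvalues Numeric vector of p-values (may contain `NA`).
#' @param eta0 Null proportion in `(0, 1]`; defaults to [estimate_eta0()] of
#'   the input for the empirical method and 1 for `"bh"`.
#' @param method `"empirical"` (scale by eta0) or `"bh"` (eta0 fixed at 1).
#' @return An object of class `"fdr_model"`: a list with `eta0`, `qvalues`
#'   (aligned with the input), `method` and `n`.
#' @export
compute_qvalues <- function(pvalues, eta0 = NULL,
                            method = c("empirical", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (length(p) && (min(p) < 0 || max(p) > 1))
    stop("p-values must lie in [0, 1]")
  if (method == "bh") eta0 <- 1
  if (is.null(eta0)) eta0 <- estimate_eta0(pvalues)
  if (eta0 <= 0 || eta0 > 1) stop("eta0 must lie in (0, 1]")
  n <- length(p)
  q <- rep(NA_real_, length(pvalues))
  if (n) {
    r <- rank(p, ties.method = "max")
    ord <- order(p, decreasing = TRUE)
    q_raw <- eta0 * n * p / r
    q_sorted <- cummin(q_raw[ord])
    qv <- numeric(n)
    qv[ord] <- pmin(q_sorted, 1)
    q[ok] <- qv
  }
  structure(list(eta0 = eta0, qvalues = q, method = method, n = n),
            class = "fdr_model")
}

#' @export
print.fdr_model <- function(x, ...) {
  cat(sprintf("FDR model (%s): eta0 = %.4f over %d p-values; %d q <= 0.05\n",
              x$method, x$eta0, x$n, sum(x$qvalues <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Subset-restricted FDR
#'
#' Re-estimates eta0 and q-values using only the p-values of a candidate
#' subset (e.g. genes previously predicted to belong to the global ECF
#' regulon). On a subset enriched for true signal the null proportion drops
#' and every subset feature's q-value can only benefit, which is how
#' restricting attention to prior candidates raises statistical power.
#'
#' @param contrast A `contrast_table` from [fit_genotype_model()].
#' @param subset Character vector of feature ids; must be non-empty and
#'   contained in the contrast table.
#' @param contrast_name Which contrast's p-values to use.
#' @param method Passed to [compute_qvalues()].
#' @return An `"fdr_model"` with an extra `features` element naming the
#'   subset rows (aligned with `qvalues`).
#' @export
restricted_fdr <- function(contrast, subset, contrast_name = "sigW/WT",
                           method = c("empirical", "bh")) {
  method <- match.arg(method)
  rows <- contrast[contrast$contrast == contrast_name, , drop = FALSE]
  if (!nrow(rows)) stop("contrast '", contrast_name, "' not in table")
  if (!length(subset)) stop("subset must be non-empty")
  missing <- setdiff(subset, rows$feature)
  if (length(missing))
    stop("subset features absent from the contrast table: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sel <- rows[match(subset, rows$feature), , drop = FALSE]
  eta0 <- if (method == "bh") 1 else estimate_eta0(sel$p)
  fm <- compute_qvalues(sel$p, eta0 = eta0, method = method)
  fm$features <- sel$feature
  fm
}

#' Estimated FDR among features passing a p-value threshold
#'
#' Returns `100 * eta0 * n * alpha / #\{p <= alpha\}` (a percentage, capped
#' at 100): the expected fraction of false discoveries among the features
#' called at p-value threshold `alpha`, under the estimated null proportion.
#'
#' @param pvalues Numeric p-values (`NA`s ignored).
#' @param eta0 Null proportion; defaults to [estimate_eta0()] of the input.
#' @param alpha Threshold in (0, 1), default 0.05.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) if no p-value
#'   passes the threshold.
#' @export
fdr_at_threshold <- function(pvalues, eta0 = NULL, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p <- pvalues[!is.na(pvalues)]
  if (is.null(eta0)) eta0 <- estimate_eta0(p)
  k <- sum(p <= alpha)
  if (k == 0L) {
    warning("no p-value at or below alpha; estimated FDR undefined")
    return(NA_real_)
  }
  min(100 * eta0 * length(p) * alpha / k, 100)
}
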