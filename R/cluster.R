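#' Correlation-cutoff clustering of condition profiles
#'
#' High-level comparison of expression profiles: average-linkage
#' hierarchical clustering of the features on the distance
#' `1 - Pearson correlation`, with the tree cut so that clusters correspond
#' to a correlation floor — cutting at height `1 - cutoff` (default cutoff
#' 0.4). Constant profiles, whose correlation is undefined, are excluded
#' with a warning and listed in the result. Cluster ids are renumbered in
#' order of first member appearance, and the cluster containing the sigma
#' factor's own gene is tagged as the reference ("core") cluster.
#'
#' @param profiles Numeric matrix, features x conditions (>= 2 features,
#'   >= 3 conditions).
#' @param cutoff Correlation cutoff in `[-1, 1]`; -1 merges everything, 1
#'   keeps only exact (duplicate-profile) merges.
#' @param reference_feature Feature id whose cluster is tagged as reference
#'   (default `"sigW"`); ignored when absent from the matrix.
#' @return A `data.frame` of class `"cluster_assignment"` with columns
#'   `feature` and `cluster`; attributes `reference_cluster` (id or `NA`)
#'   and `excluded` (constant-profile features).
#' @export
cluster_profiles <- function(profiles, cutoff = 0.4,
                             reference_feature = "sigW") {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 feature profiles")
  if (ncol(profiles) < 3L) stop("need at least 3 conditions")
  if (cutoff < -1 || cutoff > 1) stop("cutoff must lie in [-1, 1]")
  vars <- apply(profiles, 1L, stats::var)
  excluded <- rownames(profiles)[vars == 0]
  if (length(excluded)) {
    warning(length(excluded),
            " constant profile(s) excluded (correlation undefined)")
    profiles <- profiles[vars > 0, , drop = FALSE]
    if (nrow(profiles) < 2L) stop("fewer than 2 non-constant profiles left")
  }
  dm <- 1 - cor(t(profiles))
  dm[dm < 1e-12] <- 0            # duplicate profiles merge at height 0 exactly
  d <- as.dist(dm)
  tree <- hclust(d, method = "average")
  raw <- cutree(tree, h = 1 - cutoff)
  # renumber in order of first appearance so ids are deterministic
  ids <- match(raw, unique(raw))
  out <- data.frame(feature = rownames(profiles), cluster = ids,
                    stringsAsFactors = FALSE)
  ref <- if (reference_feature %in% out$feature)
    out$cluster[out$feature == reference_feature] else NA_integer_
  attr(out, "reference_cluster") <- ref
  attr(out, "excluded") <- excluded
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Stress-specific induction scores
#'
#' Scores each feature's induction under the three discriminating stresses:
#' score = mean log2 expression over the stress conditions minus the mean
#' over the unstressed reference conditions. A stress is called induced when
#' its score reaches `threshold` (default 1 log2 unit, i.e. two-fold). The
#' profile label is the hallmark of the maximal induced stress: salt
#' induction is the hallmark of the regulon under study (sigW-like), ethanol
#' of sigY-like and heat of sigM-like behaviour; features with no induced
#' stress stay unclassified.
#'
#' @param profiles Numeric matrix, features x conditions.
#' @param condition_labels Data frame with columns `condition`, `label`
#'   (`salt` / `etha` / `heat` / `ref` / `other`), as from
#'   [condition_labels()]. A non-empty `ref` set is required.
#' @param threshold Induction threshold in log2 units (default 1.0).
#' @return A `data.frame` of class `"induction_evidence"`: `feature`,
#'   `salt_score`, `ethanol_score`, `heat_score`, the three induced flags,
#'   and `profile_label`.
#' @export
score_induction <- function(profiles, condition_labels, threshold = 1.0) {
  profiles <- as.matrix(profiles)
  lab <- condition_labels
  if (!all(c("condition", "label") %in% names(lab)))
    stop("condition_labels needs columns 'condition' and 'label'")
  cols <- function(x) lab$condition[lab$label == x]
  if (!length(cols("ref")))
    stop("no reference ('ref') conditions defined")
  for (s in c("salt", "etha", "heat"))
    if (!length(cols(s))) stop("no '", s, "' conditions defined")
  missing <- setdiff(lab$condition, colnames(profiles))
  if (length(missing))
    stop("labelled conditions absent from the profile matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  ref_mean <- rowMeans(profiles[, cols("ref"), drop = FALSE])
  score <- function(s) rowMeans(profiles[, cols(s), drop = FALSE]) - ref_mean
  out <- data.frame(feature = rownames(profiles),
                    salt_score = score("salt"),
                    ethanol_score = score("etha"),
                    heat_score = score("heat"),
                    stringsAsFactors = FALSE)
  out$salt_induced <- out$salt_score >= threshold
  out$ethanol_induced <- out$ethanol_score >= threshold
  out$heat_induced <- out$heat_score >= threshold
  scores <- as.matrix(out[, c("salt_score", "ethanol_score", "heat_score")])
  induced <- as.matrix(out[, c("salt_induced", "ethanol_induced", "heat_induced")])
  labels <- c("sigW-like", "sigY-like", "sigM-like")
  pick <- function(i) {
    if (!any(induced[i, ])) return("unclassified")
    cand <- which(induced[i, ])
    labels[cand[which.max(scores[i, cand])]]
  }
  out$profile_label <- vapply(seq_len(nrow(out)), pick, character(1))
  rownames(out) <- NULL
  class(out) <- c("induction_evidence", "data.frame")
  out
}
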