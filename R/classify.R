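#' Select down- and up-regulated candidates from a contrast
#'
#' Applies the candidate thresholds (strict inequalities): down-regulated
#' candidates have effect < `-effect_threshold` and p < `p_threshold`;
#' up-regulated candidates have effect > `effect_threshold` and
#' p < `p_threshold`. Masked p-values never qualify.
#'
#' @param contrast A `contrast_table` (or any data.frame with `feature`,
#'   `contrast`, `effect`, `p`).
#' @param effect_threshold Absolute log2 effect threshold (default 0.4).
#' @param p_threshold P-value threshold (default 0.05).
#' @param contrast_name Which contrast to select from (default `"sigW/WT"`).
#' @return A list with character vectors `down` and `up`.
#' @export
select_candidates <- function(contrast, effect_threshold = 0.4,
                              p_threshold = 0.05,
                              contrast_name = "sigW/WT") {
  rows <- contrast[contrast$contrast == contrast_name, , drop = FALSE]
  if (!nrow(rows)) stop("contrast '", contrast_name, "' not in table")
  ok <- !is.na(rows$p)
  list(down = rows$feature[ok & rows$effect < -effect_threshold &
                             rows$p < p_threshold],
       up = rows$feature[ok & rows$effect > effect_threshold &
                           rows$p < p_threshold])
}

#' Assign effect-amplitude groups
#'
#' Down-regulated candidates are split by effect amplitude into group 1
#' (strongly down-regulated, effect at or below `-group_boundary`) and group
#' 2 (weakly down-regulated, effect above the boundary); the boundary value
#' itself belongs to group 1. Group 3 collects features previously reported
#' as regulon members that are nevertheless not down-regulated candidates
#' here. Everything else is `"none"`.
#'
#' @param evidence Data frame with columns `effect`, `p` and
#'   `prior_regulon` (logical).
#' @param effect_threshold,p_threshold Candidate thresholds as in
#'   [select_candidates()].
#' @param group_boundary Log2 boundary between groups 1 and 2 (default 1.5,
#'   used as -1.5 on the effect scale).
#' @return Character vector (`"1"`, `"2"`, `"3"`, `"none"`), one per row.
#' @export
assign_group <- function(evidence, effect_threshold = 0.4, p_threshold = 0.05,
                         group_boundary = 1.5) {
  down <- !is.na(evidence$p) & evidence$effect < -effect_threshold &
    evidence$p < p_threshold
  prior <- isTRUE_vec(evidence$prior_regulon)
  ifelse(down & evidence$effect <= -group_boundary, "1",
         ifelse(down, "2",
                ifelse(prior, "3", "none")))
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Classify features into regulon categories
#'
#' The deterministic rule cascade combining differential expression,
#' profile-cluster co-membership with the sigma factor's own gene, salt
#' induction, promoter-motif and operon evidence. First match wins:
#'
#' 1. down-regulated candidate in the reference cluster: `core`;
#' 2. reference-cluster member with effect < `-effect_threshold` and
#'    p < `rescue_p`: `core` (borderline rescue);
#' 3. reference-cluster member whose transcription unit already contains a
#'    core member: `core` (co-transcribed companion, e.g. a 3' UTR segment
#'    clustering with the regulon);
#' 4. down-regulated candidate induced by salt: `secondary`;
#' 5. down-regulated candidate, not salt-induced, annotated as reading
#'    through from a transcription unit holding core/secondary members:
#'    `read_through`;
#' 6. down-regulated candidate, not salt-induced, without a promoter motif:
#'    `background`;
#' 7. group-3 feature (previously reported, not down-regulated) whose
#'    profile carries another ECF hallmark (sigY-/sigM-like label) or a
#'    curated other-sigma attribution: `other_sigma`;
#' 8. otherwise `not_regulated`.
#'
#' @param evidence Data frame, one row per feature, with columns `feature`,
#'   `effect`, `p`, `in_reference_cluster` (logical), `salt_induced`
#'   (logical), `motif` (logical), `prior_regulon` (logical); optional
#'   columns `q` (numeric), `profile_label`, `other_sigma` (logical),
#'   `operon`, `operon_pos`, `downstream_of` (transcription unit read
#'   through from, `NA` if none). Missing optional columns default to
#'   inert values.
#' @param effect_threshold,p_threshold Candidate thresholds.
#' @param group_boundary Boundary between groups 1 and 2.
#' @param rescue_p Relaxed p threshold for the borderline core rescue
#'   (default 0.10).
#' @param q_threshold Threshold for the high-confidence marker (default
#'   0.05); inclusion itself uses p-values.
#' @return A `data.frame` of class `"regulon_calls"`: `feature`, `group`,
#'   `conclusion`, `down_candidate`, `up_candidate`, `high_confidence`, and
#'   the evidence columns.
#' @export
classify_regulon <- function(evidence, effect_threshold = 0.4,
                             p_threshold = 0.05, group_boundary = 1.5,
                             rescue_p = 0.10, q_threshold = 0.05) {
  req <- c("feature", "effect", "p", "in_reference_cluster", "salt_induced",
           "motif", "prior_regulon")
  missing <- setdiff(req, names(evidence))
  if (length(missing))
    stop("evidence lacks required columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(evidence$feature))
    stop("duplicated feature ids in evidence")
  ev <- as.data.frame(evidence)
  if (is.null(ev$profile_label)) ev$profile_label <- "unclassified"
  if (is.null(ev$other_sigma)) ev$other_sigma <- FALSE
  if (is.null(ev$operon)) ev$operon <- ev$feature
  if (is.null(ev$operon_pos)) ev$operon_pos <- 1L
  if (is.null(ev$downstream_of)) ev$downstream_of <- NA_character_

  ok <- !is.na(ev$p)
  down <- ok & ev$effect < -effect_threshold & ev$p < p_threshold
  up <- ok & ev$effect > effect_threshold & ev$p < p_threshold
  ref <- isTRUE_vec(ev$in_reference_cluster)
  salt <- isTRUE_vec(ev$salt_induced)
  motif <- isTRUE_vec(ev$motif)
  group <- assign_group(ev, effect_threshold, p_threshold, group_boundary)

  core <- (down & ref) |
    (ref & ev$effect < -effect_threshold & ok & ev$p < rescue_p)
  # co-transcribed companions: propagate core within a transcription unit to
  # reference-cluster members until a fixed point (deterministic)
  repeat {
    core_ops <- unique(ev$operon[core])
    add <- ref & !core & ev$operon %in% core_ops
    if (!any(add)) break
    core <- core | add
  }
  secondary <- !core & down & salt
  reg_ops <- unique(ev$operon[core | secondary])
  read_through <- !core & !secondary & down & !salt &
    !is.na(ev$downstream_of) & ev$downstream_of %in% reg_ops
  background <- !core & !secondary & !read_through & down & !salt & !motif
  other_sigma <- !core & !secondary & !read_through & !background &
    group == "3" &
    (ev$profile_label %in% c("sigY-like", "sigM-like") |
       isTRUE_vec(ev$other_sigma))

  conclusion <- rep("not_regulated", nrow(ev))
  conclusion[other_sigma] <- "other_sigma"
  conclusion[background] <- "background"
  conclusion[read_through] <- "read_through"
  conclusion[secondary] <- "secondary"
  conclusion[core] <- "core"

  out <- data.frame(feature = ev$feature, group = group,
                    conclusion = conclusion, down_candidate = down,
                    up_candidate = up,
                    high_confidence = if (!is.null(ev$q))
                      !is.na(ev$q) & ev$q < q_threshold else NA,
                    effect = ev$effect, p = ev$p,
                    in_reference_cluster = ref, salt_induced = salt,
                    motif = motif, prior_regulon = isTRUE_vec(ev$prior_regulon),
                    operon = ev$operon, operon_pos = ev$operon_pos,
                    downstream_of = ev$downstream_of,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("regulon_calls", "data.frame")
  out
}

#' @export
print.regulon_calls <- function(x, ...) {
  tab <- table(factor(x$conclusion,
                      levels = c("core", "secondary", "read_through",
                                 "background", "other_sigma", "not_regulated")))
  cat("Regulon calls over", nrow(x), "features:\n")
  for (nm in names(tab)) cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  cat(sprintf("  down candidates: %d (groups 1/2: %d/%d); up candidates: %d\n",
              sum(x$down_candidate), sum(x$group == "1"), sum(x$group == "2"),
              sum(x$up_candidate)))
  invisible(x)
}

#' Flag up-regulated features opposite the regulon
#'
#' An up-regulated feature is flagged when it overlaps, or lies within
#' `max_distance` bases of, a core/secondary regulon feature on the opposite
#' strand — the geometry in which active transcription can dampen the
#' opposite strand, so the up-regulation in the deletion mutant is a
#' positional side effect rather than regulation.
#'
#' @param up_features Character vector of up-regulated feature ids.
#' @param regulon_features Character vector of core/secondary feature ids.
#' @param annotation A `genome_annotation` holding both sets.
#' @param max_distance Maximal gap in bases (default 100).
#' @return Named logical vector along `up_features`.
#' @export
flag_opposite_strand <- function(up_features, regulon_features, annotation,
                                 max_distance = 100) {
  validate_annotation(annotation)
  gr <- annotation_granges(annotation)
  names(gr) <- annotation$feature
  up <- gr[names(gr) %in% up_features]
  reg <- gr[names(gr) %in% regulon_features]
  flag <- setNames(rep(FALSE, length(up_features)), up_features)
  if (!length(up) || !length(reg)) return(flag)
  opp <- reg
  GenomicRanges::strand(opp) <- ifelse(as.character(GenomicRanges::strand(reg)) == "+",
                                       "-", "+")
  hits <- GenomicRanges::findOverlaps(up, opp, maxgap = max_distance,
                                      ignore.strand = FALSE)
  flag[names(up)[unique(S4Vectors::queryHits(hits))]] <- TRUE
  flag
}

#' Summarize operon composition of regulon calls
#'
#' For every transcription unit with at least one core or secondary member,
#' reports the composition over those members' amplitude groups —
#' `group1_only`, `group2_only`, `mixed`, or `excluded` when no member
#' carries a group-1/2 label — and whether every group-2 member sits 3' of
#' every group-1 member in transcription order (`group2_at_end`, vacuously
#' `TRUE` when a group is absent).
#'
#' @param calls A `regulon_calls` data.frame (needs `operon`, `operon_pos`,
#'   `group`, `conclusion`).
#' @return A `data.frame` of class `"operon_summary"` with one row per
#'   operon and an attribute `"tallies"` (counts per composition).
#' @export
summarize_operons <- function(calls) {
  keep <- calls$conclusion %in% c("core", "secondary")
  members <- calls[keep, , drop = FALSE]
  if (!nrow(members)) {
    out <- data.frame(operon = character(0), n_members = integer(0),
                      n_group1 = integer(0), n_group2 = integer(0),
                      composition = character(0), group2_at_end = logical(0))
    attr(out, "tallies") <- c(group1_only = 0L, group2_only = 0L,
                              mixed = 0L, excluded = 0L)
    class(out) <- c("operon_summary", "data.frame")
    return(out)
  }
  split_ops <- split(members, members$operon)
  rows <- lapply(split_ops, function(m) {
    n1 <- sum(m$group == "1"); n2 <- sum(m$group == "2")
    comp <- if (n1 > 0L && n2 > 0L) "mixed"
    else if (n1 > 0L) "group1_only"
    else if (n2 > 0L) "group2_only"
    else "excluded"
    at_end <- if (n1 > 0L && n2 > 0L)
      min(m$operon_pos[m$group == "2"]) > max(m$operon_pos[m$group == "1"])
    else TRUE
    data.frame(operon = m$operon[1], n_members = nrow(m),
               n_group1 = n1, n_group2 = n2, composition = comp,
               group2_at_end = at_end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$operon), , drop = FALSE]
  rownames(out) <- NULL
  tl <- table(factor(out$composition,
                     levels = c("group1_only", "group2_only", "mixed",
                                "excluded")))
  attr(out, "tallies") <- setNames(as.integer(tl), names(tl))
  class(out) <- c("operon_summary", "data.frame")
  out
}

#' @export
print.operon_summary <- function(x, ...) {
  tl <- attr(x, "tallies")
  cat(sprintf("Operons with core/secondary members: %d (%d group-1 only, %d group-2 only, %d mixed)\n",
              nrow(x), tl[["group1_only"]], tl[["group2_only"]], tl[["mixed"]]))
  if (tl[["mixed"]] > 0L)
    cat(sprintf("  mixed operons with all group-2 members at the 3' end: %d of %d\n",
                sum(x$group2_at_end[x$composition == "mixed"]), tl[["mixed"]]))
  invisible(x)
}
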