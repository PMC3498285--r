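#' Packaged worked-example tables
#'
#' Loads the packaged transcriptions of the published regulon tables used by
#' the worked-example tests:
#'
#' * `table2`: the 89 genes down-regulated in the sigW mutant (effect
#'   sigW/WT < -0.4, p < 0.05), with the printed effect value, q < 0.05
#'   marker, profile cluster, promoter-motif flag, transcription-unit
#'   membership and the printed conclusion.
#' * `table3`: the 17 previously reported regulon genes that were not
#'   significant down-candidates, with the literature sigma-factor
#'   attribution used as curated evidence.
#' * `table4`: the 40 genes up-regulated in the sigW mutant, with
#'   opposite-strand neighbour annotations.
#' * `profiles`: the 79 features carrying a salt-inducible, sigW-like
#'   condition profile, partitioned into previously reported (54) and newly
#'   identified (25) members. The published work reports this set only as
#'   tallies; the packaged list is a reconstruction from the
#'   core/secondary table rows plus the rescued borderline gene, and the
#'   newly-identified flags follow the described novel segments.
#'
#' Per-gene p-values are not printed in the source tables (except the one
#' borderline rescue at p = 0.08); the fixtures carry surrogate p-values
#' consistent with the table footnotes (0.01 for candidate rows, 0.5 for
#' non-candidates). The `.` sentinel in optional columns reads as `NA`.
#'
#' @return A list with data.frames `table2`, `table3`, `table4`, `profiles`.
#' @export
regulon_fixtures <- function() {
  read_fx <- function(name) {
    path <- system.file("extdata", name, package = "tilereg", mustWork = TRUE)
    df <- read.delim(path, stringsAsFactors = FALSE)
    for (col in names(df))
      if (is.character(df[[col]])) df[[col]][df[[col]] == "."] <- NA
    df
  }
  t2 <- read_fx("table2_downregulated.tsv")
  t3 <- read_fx("table3_prior_regulon.tsv")
  t4 <- read_fx("table4_upregulated.tsv")
  pf <- read_fx("salt_profile_calls.tsv")
  t2$motif <- t2$motif == "Yes"
  t3$motif <- t3$motif == "Yes"
  list(table2 = t2, table3 = t3, table4 = t4, profiles = pf)
}

#' Contrast table assembled from the packaged tables
#'
#' Stacks the fixture tables into a `contrast_table`-shaped data.frame for
#' the sigW/WT comparison, suitable for [select_candidates()].
#'
#' @param fixtures Output of [regulon_fixtures()].
#' @return A data.frame with `feature`, `contrast`, `effect`, `p`.
#' @export
fixture_contrast <- function(fixtures = regulon_fixtures()) {
  pick <- function(df) df[, c("feature", "effect", "p")]
  out <- rbind(pick(fixtures$table2), pick(fixtures$table3),
               pick(fixtures$table4))
  out <- data.frame(feature = out$feature, contrast = "sigW/WT",
                    effect = out$effect, p = out$p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classifier evidence assembled from the packaged tables
#'
#' Joins the down-regulated and prior-regulon tables into the evidence frame
#' [classify_regulon()] consumes. Reference-cluster membership is the
#' printed profile-cluster id equal to `reference_cluster` (the cluster
#' holding the sigma factor's own gene, C9 in the source annotation).
#'
#' @param fixtures Output of [regulon_fixtures()].
#' @param reference_cluster Printed cluster id of the reference cluster.
#' @return A data.frame ready for [classify_regulon()], with the printed
#'   conclusions carried along as `call_expected` for comparison.
#' @export
fixture_evidence <- function(fixtures = regulon_fixtures(),
                             reference_cluster = "C9") {
  t2 <- fixtures$table2
  t3 <- fixtures$table3
  ev2 <- data.frame(feature = t2$feature, effect = t2$effect, p = t2$p,
                    in_reference_cluster = t2$cluster == reference_cluster,
                    salt_induced = t2$salt_induced, motif = t2$motif,
                    prior_regulon = t2$prior_regulon,
                    profile_label = ifelse(t2$salt_induced, "sigW-like",
                                           "unclassified"),
                    other_sigma = FALSE, operon = t2$operon,
                    operon_pos = t2$operon_pos,
                    downstream_of = t2$downstream_of,
                    q_lt_0.05 = t2$q_lt_0.05,
                    call_expected = t2$call_expected,
                    stringsAsFactors = FALSE)
  ev3 <- data.frame(feature = t3$feature, effect = t3$effect, p = t3$p,
                    in_reference_cluster = t3$cluster == reference_cluster,
                    salt_induced = t3$salt_induced, motif = t3$motif,
                    prior_regulon = t3$prior_regulon,
                    profile_label = t3$profile_label,
                    other_sigma = t3$other_sigma, operon = t3$operon,
                    operon_pos = t3$operon_pos,
                    downstream_of = NA_character_,
                    q_lt_0.05 = FALSE,
                    call_expected = t3$call_expected,
                    stringsAsFactors = FALSE)
  out <- rbind(ev2, ev3)
  rownames(out) <- NULL
  out
}
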