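#' Run the full regulon-definition pipeline on simulated data
#'
#' Executes every stage end to end: simulate (annotation, ground truth,
#' probe signals, condition profiles) -> smooth -> aggregate ->
#' quantile-normalize -> flag outlier arrays -> re-normalize included
#' samples -> per-feature genotype model -> global and subset-restricted
#' FDR -> profile clustering and induction scoring -> regulon
#' classification -> operon and opposite-strand summaries. When `outdir` is
#' given, every stage's table, the fully resolved configuration (YAML) and a
#' run log (parameters, excluded arrays, masked features, tallies) are
#' written; numeric output uses a fixed decimal format so reruns with the
#' same seed are byte-identical.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional output directory (created if needed).
#' @param window Smoothing window in probes ([smooth_signal()]).
#' @param min_correlation Outlier-array threshold ([flag_outlier_arrays()]).
#' @param cutoff Profile-clustering correlation cutoff ([cluster_profiles()]).
#' @param induction_threshold Log2 induction threshold ([score_induction()]).
#' @param effect_threshold,p_threshold,group_boundary,rescue_p,q_threshold
#'   Classifier constants ([classify_regulon()]).
#' @param contrasts Genotype contrasts for [fit_genotype_model()].
#' @return A list of class `"tilereg_run"` with all stage results
#'   (`annotation`, `truth`, `design`, `expression`, `contrasts`, `fdr`,
#'   `clusters`, `induction`, `calls`, `operons`, `opposite_strand`,
#'   `masked`, `outlier_log`, `params`).
#' @examples
#' \donttest{
#' run <- run_pipeline(simulation_config(n_operons = 20,
#'                                       genome_length = 80000))
#' print(run)
#' }
#' @export
run_pipeline <- function(config = simulation_config(), outdir = NULL,
                         window = 3L, min_correlation = 0.8, cutoff = 0.4,
                         induction_threshold = 1.0, effect_threshold = 0.4,
                         p_threshold = 0.05, group_boundary = 1.5,
                         rescue_p = 0.10, q_threshold = 0.05,
                         contrasts = c("sigW/WT", "rasP/WT", "prsW/WT",
                                       "rasP/sigW", "prsW/sigW")) {
  validate_config(config)
  params <- list(window = window, min_correlation = min_correlation,
                 cutoff = cutoff, induction_threshold = induction_threshold,
                 effect_threshold = effect_threshold,
                 p_threshold = p_threshold, group_boundary = group_boundary,
                 rescue_p = rescue_p, q_threshold = q_threshold,
                 contrasts = contrasts)

  annotation <- generate_annotation(config)
  truth <- generate_truth(annotation, config)
  design <- make_design(config)
  probes <- simulate_probe_signals(annotation, truth, design, config)
  profiles <- simulate_condition_profiles(annotation, truth, config)
  labels <- attr(profiles, "condition_labels")

  smoothed <- smooth_signal(probes, window)
  expr <- suppressMessages(aggregate_features(smoothed, annotation))
  masked <- attr(expr, "masked")
  expr <- expr[stats::complete.cases(expr), , drop = FALSE]

  normalized <- quantile_normalize(expr)
  design <- suppressMessages(flag_outlier_arrays(normalized, design,
                                                 min_correlation))
  outlier_log <- attr(design, "outlier_log")
  included <- design$sample[design$included]
  normalized <- quantile_normalize(expr[, included, drop = FALSE])

  fit <- fit_genotype_model(normalized, design, contrasts)

  # global empirical q per contrast; restricted q on the prior ECF candidate
  # set (motif or previously-reported flag)
  subset_ids <- annotation$feature[(annotation$motif | annotation$prior_regulon)]
  subset_ids <- intersect(subset_ids, rownames(normalized))
  fit$q <- NA_real_
  fit$q_restricted <- NA_real_
  fdr_models <- list()
  for (cn in contrasts) {
    rows <- which(fit$contrast == cn)
    fm <- compute_qvalues(fit$p[rows],
                          eta0 = suppressWarnings(estimate_eta0(fit$p[rows])))
    fit$q[rows] <- fm$qvalues
    fdr_models[[cn]] <- fm
    if (length(subset_ids) >= 2L) {
      rf <- suppressWarnings(restricted_fdr(fit, subset_ids,
                                            contrast_name = cn))
      fit$q_restricted[rows[match(subset_ids, fit$feature[rows])]] <- rf$qvalues
    }
  }

  keep <- intersect(rownames(profiles), rownames(normalized))
  clusters <- cluster_profiles(profiles[keep, , drop = FALSE], cutoff,
                               reference_feature = "sigW")
  induction <- score_induction(profiles[keep, , drop = FALSE], labels,
                               induction_threshold)

  sig <- fit[fit$contrast == "sigW/WT", ]
  feats <- rownames(normalized)
  ref_cluster <- attr(clusters, "reference_cluster")
  ann_ix <- match(feats, annotation$feature)
  evidence <- data.frame(
    feature = feats,
    effect = sig$effect[match(feats, sig$feature)],
    p = sig$p[match(feats, sig$feature)],
    q = sig$q[match(feats, sig$feature)],
    in_reference_cluster = !is.na(ref_cluster) &
      clusters$cluster[match(feats, clusters$feature)] %in% ref_cluster,
    salt_induced = induction$salt_induced[match(feats, induction$feature)],
    profile_label = induction$profile_label[match(feats, induction$feature)],
    motif = annotation$motif[ann_ix],
    prior_regulon = annotation$prior_regulon[ann_ix],
    operon = annotation$operon[ann_ix],
    operon_pos = annotation$operon_pos[ann_ix],
    stringsAsFactors = FALSE)
  evidence$salt_induced[is.na(evidence$salt_induced)] <- FALSE
  evidence$profile_label[is.na(evidence$profile_label)] <- "unclassified"

  calls <- classify_regulon(evidence, effect_threshold, p_threshold,
                            group_boundary, rescue_p, q_threshold)
  operons <- summarize_operons(calls)
  up_ids <- calls$feature[calls$up_candidate]
  reg_ids <- calls$feature[calls$conclusion %in% c("core", "secondary")]
  opposite <- flag_opposite_strand(up_ids, reg_ids, annotation)

  run <- list(annotation = annotation, truth = truth, design = design,
              probes = probes, profiles = profiles,
              expression = normalized, contrasts = fit, fdr = fdr_models,
              clusters = clusters, induction = induction, calls = calls,
              operons = operons, opposite_strand = opposite,
              masked = masked, outlier_log = outlier_log,
              config = config, params = params)
  class(run) <- "tilereg_run"

  if (!is.null(outdir)) write_run(run, outdir)
  invisible(run)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(outdir, name)
  write_annotation(run$annotation, fp("annotation.gff3"))
  write_tsv(run$truth, fp("truth.tsv"))
  write_tsv(run$design, fp("design.tsv"))
  write_tsv(run$probes, fp("probe_signals.tsv"))
  write_matrix_tsv(run$profiles, fp("condition_profiles.tsv"))
  write_tsv(attr(run$profiles, "condition_labels"), fp("condition_labels.tsv"))
  write_matrix_tsv(run$expression, fp("expression_normalized.tsv"))
  write_tsv(run$contrasts, fp("contrasts.tsv"))
  write_tsv(run$clusters, fp("clusters.tsv"))
  write_tsv(run$induction, fp("induction.tsv"))
  write_tsv(run$calls, fp("regulon_calls.tsv"))
  write_tsv(run$operons, fp("operon_summary.tsv"))
  write_tsv(data.frame(feature = names(run$opposite_strand),
                       opposite_regulon = unname(run$opposite_strand)),
            fp("opposite_strand.tsv"))
  resolved <- c(unclass(run$config), run$params)
  yaml::write_yaml(resolved, fp("config_resolved.yaml"))

  tl <- attr(run$operons, "tallies")
  log_lines <- c(
    sprintf("features analyzed: %d", nrow(run$calls)),
    sprintf("features masked (no eligible probes): %d [%s]",
            length(run$masked), paste(run$masked, collapse = ", ")),
    sprintf("arrays excluded: %s",
            if (any(run$outlier_log$excluded))
              paste(sprintf("%s (r = %.3f)",
                            run$outlier_log$sample[run$outlier_log$excluded],
                            run$outlier_log$correlation[run$outlier_log$excluded]),
                    collapse = ", ") else "none"),
    sprintf("down candidates: %d (group 1: %d, group 2: %d); up candidates: %d",
            sum(run$calls$down_candidate), sum(run$calls$group == "1"),
            sum(run$calls$group == "2"), sum(run$calls$up_candidate)),
    sprintf("conclusions: %s",
            paste(sprintf("%s = %d", names(table(run$calls$conclusion)),
                          as.integer(table(run$calls$conclusion))),
                  collapse = ", ")),
    sprintf("operons with core/secondary members: %d (group1_only %d, group2_only %d, mixed %d)",
            nrow(run$operons), tl[["group1_only"]], tl[["group2_only"]],
            tl[["mixed"]]))
  writeLines(log_lines, fp("run_log.txt"))
  invisible(outdir)
}

#' @export
print.tilereg_run <- function(x, ...) {
  cat("Regulon-definition pipeline run\n")
  cat(sprintf("  %d features, %d/%d arrays included, %d masked features\n",
              nrow(x$calls), sum(x$design$included), nrow(x$design),
              length(x$masked)))
  print(x$calls)
  print(x$operons)
  invisible(x)
}
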