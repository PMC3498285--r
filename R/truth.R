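#' Plant ground-truth effects and profile structure
#'
#' Draws the planted log2 knockout effect for every feature of a synthetic
#' annotation and records the remaining ground truth (regulon membership,
#' planted profile cluster, stress-induction class) needed by recovery tests.
#' Features of regulon operons draw their sigW/WT effect from the
#' two-component (strong/weak) mixture; all other features have effect 0.
#' The rasP/WT and prsW/WT effects are the sigW effect times the configured
#' attenuations. With `weak_at_operon_end = TRUE` the mixture component is
#' determined by operon position (3'-half members are weak) instead of being
#' drawn independently, the alternative generating mechanism for the bimodal
#' down-regulation pattern.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config The [simulation_config()] used for the annotation.
#' @return A `data.frame` of class `"simulation_truth"`, one row per feature:
#'   `feature`, `membership` (`core` / `background` / `antisense_partner`),
#'   `component` (`strong` / `weak` / `NA`), `effect_sigW`, `effect_rasP`,
#'   `effect_prsW` (log2 units), `baseline` (log2 expression in WT),
#'   `cluster` (planted profile cluster id) and `profile_class`
#'   (`sigW` / `sigY` / `sigM` / `none`).
#' @export
generate_truth <- function(annotation, config) {
  validate_config(config)
  validate_annotation(annotation)
  set.seed(config$seed + 2L)

  n <- nrow(annotation)
  is_reg <- annotation$regulon_operon & annotation$type == "gene"
  mix <- config$effect_mixture

  component <- rep(NA_character_, n)
  effect <- numeric(n)
  idx <- which(is_reg)
  if (length(idx)) {
    if (config$weak_at_operon_end) {
      op_len <- ave(annotation$operon_pos, annotation$operon, FUN = max)
      comp <- ifelse(annotation$operon_pos[idx] > op_len[idx] / 2, "weak", "strong")
    } else {
      comp <- ifelse(runif(length(idx)) < mix$weight, "strong", "weak")
    }
    component[idx] <- comp
    mean_c <- ifelse(comp == "strong", mix$strong[["mean"]], mix$weak[["mean"]])
    sd_c <- ifelse(comp == "strong", mix$strong[["sd"]], mix$weak[["sd"]])
    effect[idx] <- rnorm(length(idx), mean_c, sd_c)
  }

  membership <- ifelse(is_reg, "core", "background")
  as_of <- annotation$antisense_of
  partner_reg <- !is.na(as_of) & as_of %in% annotation$feature[is_reg]
  membership[partner_reg] <- "antisense_partner"

  # planted condition-profile structure: cluster 1 is the regulon's own
  # cluster; everything else is spread over the remaining clusters
  cluster <- integer(n)
  cluster[is_reg] <- 1L
  others <- which(!is_reg)
  if (config$n_clusters > 1L && length(others)) {
    pool <- 2:config$n_clusters
    cluster[others] <- pool[sample.int(length(pool), length(others),
                                       replace = TRUE)]
  } else {
    cluster[others] <- 1L
  }

  profile_class <- ifelse(is_reg, "sigW", "none")
  bg <- which(membership == "background" & annotation$type == "gene")
  n_y <- min(config$n_sigY_decoys, length(bg))
  decoy_y <- bg[sample.int(length(bg), n_y)]
  bg2 <- setdiff(bg, decoy_y)
  n_m <- min(config$n_sigM_decoys, length(bg2))
  decoy_m <- bg2[sample.int(length(bg2), n_m)]
  profile_class[decoy_y] <- "sigY"
  profile_class[decoy_m] <- "sigM"
  # decoys share one latent response each so they form their own clusters
  if (config$n_clusters > 1L) {
    cluster[decoy_y] <- config$n_clusters + 1L
    cluster[decoy_m] <- config$n_clusters + 2L
  }

  truth <- data.frame(feature = annotation$feature,
                      membership = membership,
                      component = component,
                      effect_sigW = effect,
                      effect_rasP = effect * config$attenuation_rasP,
                      effect_prsW = effect * config$attenuation_prsW,
                      baseline = runif(n, 6, 10),
                      cluster = cluster,
                      profile_class = profile_class,
                      stringsAsFactors = FALSE)
  class(truth) <- c("simulation_truth", "data.frame")
  truth
}
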