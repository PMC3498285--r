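#' Simulate multi-condition expression profiles
#'
#' Emulates a condition compendium: every planted cluster shares a latent
#' condition response (drawn once per cluster), each feature adds independent
#' noise, and stress-inducible classes receive an additional log2 induction
#' in their hallmark conditions — regulon (sigW-like) features in the salt
#' conditions, sigY-like decoys in the ethanol conditions and sigM-like
#' decoys in the heat conditions. Salt induction is what downstream evidence
#' scoring uses to separate the regulon from the other ECF regulons.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [generate_truth()].
#' @param config The [simulation_config()].
#' @return A numeric matrix, features x conditions (log2 scale), with an
#'   attribute `"condition_labels"` equal to [condition_labels]`(config)`.
#' @export
simulate_condition_profiles <- function(annotation, truth, config) {
  validate_config(config)
  set.seed(config$seed + 4L)

  n <- nrow(truth)
  conds <- sprintf("cond_%03d", seq_len(config$n_conditions))
  clusters <- sort(unique(truth$cluster))
  latent <- matrix(rnorm(length(clusters) * config$n_conditions,
                         0, config$cluster_sd),
                   nrow = length(clusters),
                   dimnames = list(as.character(clusters), conds))
  mat <- latent[as.character(truth$cluster), , drop = FALSE] +
    matrix(rnorm(n * config$n_conditions, 0, config$profile_noise_sd),
           nrow = n)
  mat <- mat + truth$baseline
  dimnames(mat) <- list(truth$feature, conds)

  induce <- function(class, cols) {
    rows <- truth$profile_class == class
    mat[rows, cols] <<- mat[rows, cols] + config$induction_size
  }
  induce("sigW", config$salt_conditions)
  induce("sigY", config$ethanol_conditions)
  induce("sigM", config$heat_conditions)

  attr(mat, "condition_labels") <- condition_labels(config)
  mat
}

#' Condition labels for a simulated compendium
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` with columns `condition` and `label`
#'   (`salt` / `etha` / `heat` / `ref` / `other`).
#' @export
condition_labels <- function(config) {
  label <- rep("other", config$n_conditions)
  label[config$salt_conditions] <- "salt"
  label[config$ethanol_conditions] <- "etha"
  label[config$heat_conditions] <- "heat"
  label[config$reference_conditions] <- "ref"
  data.frame(condition = sprintf("cond_%03d", seq_len(config$n_conditions)),
             label = label, stringsAsFactors = FALSE)
}
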