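#' Configuration for the synthetic tiling-array study
#'
#' Builds the configuration object consumed by [generate_annotation()],
#' [generate_truth()], [simulate_probe_signals()] and
#' [simulate_condition_profiles()]. The defaults emulate the study design the
#' analysis is built for: four genotypes (WT and the sigW, rasP and prsW
#' mutants) with three biological replicates each, a planted regulon whose
#' log2 knockout effects are drawn from a bimodal (strong/weak) mixture,
#' attenuated effects in the protease mutants, and a multi-condition profile
#' compendium with salt-, ethanol- and heat-specific induction.
#'
#' @param genome_length Genome size in bases for the simulated chromosome.
#' @param n_operons Number of transcription units to place.
#' @param genes_per_operon Integer range `c(min, max)` of features per operon.
#' @param probe_step Tiling step between probe starts, in bases (per strand).
#' @param probe_length Probe length in bases.
#' @param n_replicates Biological replicates per genotype.
#' @param regulon_fraction Fraction of operons planted as regulon members.
#' @param effect_mixture List with components `strong = c(mean, sd)`,
#'   `weak = c(mean, sd)` and `weight` (probability of the strong component)
#'   describing the bimodal distribution of planted sigW/WT log2 effects.
#' @param attenuation_rasP,attenuation_prsW Multipliers in (0, 1] applied to
#'   the planted sigW effect to obtain the rasP/WT and prsW/WT effects.
#' @param noise_sd Log2-scale Gaussian probe noise standard deviation.
#' @param array_distortion Strength of the per-array monotone signal
#'   distortion (0 disables it).
#' @param outlier_array If `TRUE`, one prsW array is replaced by a profile
#'   drawn from an unrelated baseline, mimicking a stationary-phase-like
#'   hybridization failure.
#' @param nonunique_fraction Fraction of probes flagged as not uniquely
#'   matching the genome (their signal is corrupted and they must be ignored
#'   during aggregation).
#' @param antisense_fraction Fraction of features given an opposite-strand
#'   partner feature overlapping their 5' region.
#' @param internal_promoter_fraction,terminator_fraction Fractions of
#'   multi-gene operons receiving an internal promoter mark (before a
#'   non-first member) or a terminator mark (after a non-last member).
#' @param prior_regulon_fraction Probability that a planted regulon feature
#'   carries the "previously reported" flag.
#' @param weak_at_operon_end If `TRUE`, planted effects within regulon operons
#'   are forced to the weak mixture component for 3'-half members (the
#'   operon-position mechanism for bimodality); otherwise components are
#'   drawn independently per feature.
#' @param n_conditions Number of conditions in the profile compendium.
#' @param salt_conditions,ethanol_conditions,heat_conditions,reference_conditions
#'   Disjoint condition index sets for the three stresses and the unstressed
#'   reference.
#' @param induction_size Log2 induction added in the matching stress
#'   conditions for regulon (salt), sigY-like decoy (ethanol) and sigM-like
#'   decoy (heat) features.
#' @param n_sigY_decoys,n_sigM_decoys Numbers of background features planted
#'   as ethanol-inducible (sigY-like) and heat-inducible (sigM-like) decoys.
#' @param n_clusters Number of planted condition-profile clusters (cluster 1
#'   is the regulon's own cluster).
#' @param cluster_sd Standard deviation of the shared latent condition
#'   response within a cluster.
#' @param profile_noise_sd Independent per-feature noise added to profiles.
#' @param seed Root seed; all randomness in the generators derives from it.
#'
#' @return A list of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(n_operons = 5, genome_length = 20000)
#' ann <- generate_annotation(cfg)
#' @export
simulation_config <- function(genome_length = 400000,
                              n_operons = 100,
                              genes_per_operon = c(1L, 4L),
                              probe_step = 22,
                              probe_length = 50,
                              n_replicates = 3,
                              regulon_fraction = 0.05,
                              effect_mixture = list(strong = c(mean = -2.5, sd = 0.5),
                                                    weak = c(mean = -0.9, sd = 0.3),
                                                    weight = 0.5),
                              attenuation_rasP = 0.4,
                              attenuation_prsW = 0.35,
                              noise_sd = 0.25,
                              array_distortion = 0.3,
                              outlier_array = FALSE,
                              nonunique_fraction = 0.05,
                              antisense_fraction = 0.10,
                              internal_promoter_fraction = 0.25,
                              terminator_fraction = 0.25,
                              prior_regulon_fraction = 0.6,
                              weak_at_operon_end = FALSE,
                              n_conditions = 104,
                              salt_conditions = 1:6,
                              ethanol_conditions = 7:12,
                              heat_conditions = 13:18,
                              reference_conditions = 19:24,
                              induction_size = 2,
                              n_sigY_decoys = 12,
                              n_sigM_decoys = 12,
                              n_clusters = 10,
                              cluster_sd = 1.0,
                              profile_noise_sd = 0.2,
                              seed = 1L) {
  config <- list(genome_length = as.integer(genome_length),
                 n_operons = as.integer(n_operons),
                 genes_per_operon = as.integer(genes_per_operon),
                 probe_step = as.integer(probe_step),
                 probe_length = as.integer(probe_length),
                 n_replicates = as.integer(n_replicates),
                 regulon_fraction = regulon_fraction,
                 effect_mixture = effect_mixture,
                 attenuation_rasP = attenuation_rasP,
                 attenuation_prsW = attenuation_prsW,
                 noise_sd = noise_sd,
                 array_distortion = array_distortion,
                 outlier_array = isTRUE(outlier_array),
                 nonunique_fraction = nonunique_fraction,
                 antisense_fraction = antisense_fraction,
                 internal_promoter_fraction = internal_promoter_fraction,
                 terminator_fraction = terminator_fraction,
                 prior_regulon_fraction = prior_regulon_fraction,
                 weak_at_operon_end = isTRUE(weak_at_operon_end),
                 n_conditions = as.integer(n_conditions),
                 salt_conditions = as.integer(salt_conditions),
                 ethanol_conditions = as.integer(ethanol_conditions),
                 heat_conditions = as.integer(heat_conditions),
                 reference_conditions = as.integer(reference_conditions),
                 induction_size = induction_size,
                 n_sigY_decoys = as.integer(n_sigY_decoys),
                 n_sigM_decoys = as.integer(n_sigM_decoys),
                 n_clusters = as.integer(n_clusters),
                 cluster_sd = cluster_sd,
                 profile_noise_sd = profile_noise_sd,
                 seed = as.integer(seed))
  class(config) <- "simulation_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with(config, {
    if (probe_step < 1L) stop("probe_step must be >= 1")
    if (probe_length < 1L) stop("probe_length must be >= 1")
    if (n_operons < 1L || n_replicates < 1L || n_conditions < 1L)
      stop("all counts must be >= 1")
    if (length(genes_per_operon) != 2L || any(genes_per_operon < 1L) ||
        genes_per_operon[1] > genes_per_operon[2])
      stop("genes_per_operon must be an increasing integer range c(min, max)")
    w <- effect_mixture$weight
    if (is.null(w) || w < 0 || w > 1)
      stop("effect_mixture$weight must lie in [0, 1]")
    if (attenuation_rasP <= 0 || attenuation_rasP > 1 ||
        attenuation_prsW <= 0 || attenuation_prsW > 1)
      stop("attenuations must lie in (0, 1]")
    if (regulon_fraction < 0 || regulon_fraction > 1)
      stop("regulon_fraction must lie in [0, 1]")
    sets <- list(salt_conditions, ethanol_conditions, heat_conditions,
                 reference_conditions)
    all_idx <- unlist(sets)
    if (anyDuplicated(all_idx))
      stop("salt/ethanol/heat/reference condition index sets must be disjoint")
    if (any(all_idx < 1L) || any(all_idx > n_conditions))
      stop("condition index sets must lie within 1..n_conditions")
  })
  invisible(config)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic tiling-array study configuration\n")
  cat(sprintf("  genome: %d bp, %d operons, probes every %d bp (length %d)\n",
              x$genome_length, x$n_operons, x$probe_step, x$probe_length))
  cat(sprintf("  design: 4 genotypes x %d replicates; regulon fraction %.2f\n",
              x$n_replicates, x$regulon_fraction))
  cat(sprintf("  effects: strong N(%.2f, %.2f) / weak N(%.2f, %.2f), weight %.2f\n",
              x$effect_mixture$strong[["mean"]], x$effect_mixture$strong[["sd"]],
              x$effect_mixture$weak[["mean"]], x$effect_mixture$weak[["sd"]],
              x$effect_mixture$weight))
  cat(sprintf("  noise sd %.2f, distortion %.2f, outlier array: %s\n",
              x$noise_sd, x$array_distortion, x$outlier_array))
  cat(sprintf("  profiles: %d conditions, induction %.1f log2, seed %d\n",
              x$n_conditions, x$induction_size, x$seed))
  invisible(x)
}
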