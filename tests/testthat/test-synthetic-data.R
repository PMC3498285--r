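test_that("generators are deterministic under a fixed seed and config", {
  cfg <- small_config()
  a1 <- generate_annotation(cfg); a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  t1 <- generate_truth(a1, cfg); t2 <- generate_truth(a2, cfg)
  expect_identical(t1, t2)
  d <- make_design(cfg)
  p1 <- simulate_probe_signals(a1, t1, d, cfg)
  p2 <- simulate_probe_signals(a1, t1, d, cfg)
  expect_identical(p1, p2)
  m1 <- simulate_condition_profiles(a1, t1, cfg)
  m2 <- simulate_condition_profiles(a1, t1, cfg)
  expect_identical(m1, m2)
})

test_that("annotation layout honours the minimal and degenerate cases", {
  cfg <- simulation_config(n_operons = 1, genes_per_operon = c(3, 3),
                           genome_length = 20000, antisense_fraction = 0,
                           seed = 5)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 3L)
  expect_true(all(diff(ann$start) > 0))
  expect_equal(length(unique(ann$strand)), 1L)
  expect_true(all(ann$end >= ann$start))
  expect_true(all(is.na(ann$antisense_of)))

  # antisense fraction 0 emits no opposite-strand partners even at scale
  ann2 <- generate_annotation(simulation_config(n_operons = 20,
                                                genome_length = 100000,
                                                antisense_fraction = 0,
                                                seed = 6))
  expect_false(any(ann2$type == "antisense"))
})

test_that("an undersized genome raises a sizing error naming the deficit", {
  cfg <- simulation_config(n_operons = 30, genome_length = 5000, seed = 1)
  expect_error(generate_annotation(cfg), "too short.*deficit",)
})

test_that("planted effects follow the mixture, attenuation and zero cases", {
  cfg <- small_config(regulon_fraction = 0)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  expect_true(all(truth$effect_sigW == 0))
  expect_true(all(truth$effect_rasP == 0))

  cfg2 <- small_config(regulon_fraction = 0.5, attenuation_rasP = 0.3,
                       attenuation_prsW = 0.6)
  ann2 <- generate_annotation(cfg2)
  truth2 <- generate_truth(ann2, cfg2)
  expect_equal(truth2$effect_rasP, truth2$effect_sigW * 0.3)
  expect_equal(truth2$effect_prsW, truth2$effect_sigW * 0.6)
  expect_true(all(truth2$effect_sigW[truth2$membership == "core"] != 0))
  expect_true(all(truth2$effect_sigW[truth2$membership == "background"] == 0))
  expect_equal(anyDuplicated(truth2$feature), 0L)
})

test_that("the planted effect distribution is bimodal at the configured modes", {
  cfg <- simulation_config(n_operons = 3000, genes_per_operon = c(3, 4),
                           genome_length = 13000000, regulon_fraction = 1,
                           antisense_fraction = 0, seed = 9)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  eff <- truth$effect_sigW[truth$membership == "core"]
  expect_gt(length(eff), 9000)
  dens <- stats::density(eff, bw = 0.1)
  # local maxima of the kernel density
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  modes <- dens$x[peaks[order(y[peaks], decreasing = TRUE)][1:2]]
  modes <- sort(modes)
  expect_lt(abs(modes[1] - (-2.5)), 0.15)
  expect_lt(abs(modes[2] - (-0.9)), 0.15)
})

test_that("probe tiling conserves the probe count on both strands", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  probes <- simulate_probe_signals(ann, truth, make_design(cfg), cfg)
  per_strand <- floor((cfg$genome_length - cfg$probe_length) / cfg$probe_step) + 1
  expect_equal(nrow(probes), 2L * per_strand)
  expect_equal(sum(probes$strand == "+"), per_strand)
})

test_that("noise-free signals reproduce planted structure exactly", {
  cfg <- small_config(noise_sd = 0, array_distortion = 0,
                      nonunique_fraction = 0, regulon_fraction = 0)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  design <- make_design(cfg)
  probes <- simulate_probe_signals(ann, truth, design, cfg)
  cols <- design$sample
  for (j in cols[-1]) expect_equal(probes[[j]], probes[[cols[1]]])

  # with planted effects, the within-feature probe mean differs by exactly
  # the planted effect between mutant and parental arrays
  cfg2 <- small_config(noise_sd = 0, array_distortion = 0,
                       nonunique_fraction = 0, regulon_fraction = 0.4)
  ann2 <- generate_annotation(cfg2)
  truth2 <- generate_truth(ann2, cfg2)
  probes2 <- simulate_probe_signals(ann2, truth2, design, cfg2)
  reg_feats <- truth2$feature[truth2$membership == "core"]
  for (f in reg_feats[1:5]) {
    i <- match(f, ann2$feature)
    sel <- probes2$strand == ann2$strand[i] & probes2$start >= ann2$start[i] &
      probes2$end <= ann2$end[i]
    if (!any(sel)) next
    diffs <- mean(probes2$sigW_1[sel]) - mean(probes2$WT_1[sel])
    expect_equal(diffs, truth2$effect_sigW[match(f, truth2$feature)])
  }
})

test_that("noisy per-feature mean differences respect the normal-theory bound", {
  cfg <- simulation_config(n_operons = 80, genome_length = 320000,
                           noise_sd = 0.25, array_distortion = 0,
                           nonunique_fraction = 0, regulon_fraction = 0.5,
                           antisense_fraction = 0, seed = 21)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  design <- make_design(cfg)
  probes <- simulate_probe_signals(ann, truth, design, cfg)
  wt <- as.matrix(probes[, design$sample[design$genotype == "WT"]])
  sw <- as.matrix(probes[, design$sample[design$genotype == "sigW"]])
  n_checked <- 0L
  within <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    sel <- probes$strand == ann$strand[i] & probes$start >= ann$start[i] &
      probes$end <= ann$end[i]
    m <- sum(sel)
    if (m < 5L) next
    diff_mean <- mean(sw[sel, ]) - mean(wt[sel, ])
    planted <- truth$effect_sigW[match(ann$feature[i], truth$feature)]
    bound <- 3 * 0.25 * sqrt(2 / (3 * m))
    n_checked <- n_checked + 1L
    within[n_checked] <- abs(diff_mean - planted) < bound
    # nothing should ever stray far beyond the bound
    expect_lt(abs(diff_mean - planted), 1.5 * bound)
  }
  expect_gte(n_checked, 150L)
  # the 3-sigma normal-theory bound covers ~99.7%; allow the expected
  # handful of boundary exceedances over hundreds of features
  expect_gte(mean(within[seq_len(n_checked)]), 0.98)
})

test_that("condition profiles carry planted cluster and induction structure", {
  cfg <- small_config(profile_noise_sd = 0)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  prof <- simulate_condition_profiles(ann, truth, cfg)
  # two same-cluster features: identical up to baseline => correlation 1
  cl <- truth$cluster
  pair <- which(cl == cl[duplicated(cl)][1])[1:2]
  expect_equal(cor(prof[pair[1], ], prof[pair[2], ]), 1)

  # salt induction is exact once the shared latent response is switched off
  cfg0 <- small_config(profile_noise_sd = 0, cluster_sd = 0)
  truth0 <- generate_truth(generate_annotation(cfg0), cfg0)
  prof0 <- simulate_condition_profiles(generate_annotation(cfg0), truth0, cfg0)
  labels <- attr(prof0, "condition_labels")
  sw <- which(truth0$profile_class == "sigW")[1]
  salt_cols <- labels$condition[labels$label == "salt"]
  ref_cols <- labels$condition[labels$label == "ref"]
  expect_equal(mean(prof0[sw, salt_cols]) - mean(prof0[sw, ref_cols]),
               cfg0$induction_size)
})

test_that("a design with an unknown genotype is rejected", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  design <- make_design(cfg)
  design$genotype[1] <- "sigX"
  expect_error(simulate_probe_signals(ann, truth, design, cfg),
               "unknown genotype")
})
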