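make_probe_df <- function(starts, signal, strand = "+", len = 10L,
                          unique_match = TRUE) {
  data.frame(probe = sprintf("p%03d", seq_along(starts)),
             start = starts, end = starts + len - 1L, strand = strand,
             unique_match = unique_match, s1 = signal,
             stringsAsFactors = FALSE)
}

test_that("running-median smoothing: identity, spike removal, parameter checks", {
  p <- make_probe_df(seq(1, 100, by = 20), c(0, 0, 10, 0, 0))
  expect_identical(smooth_signal(p, 1L), p)
  sm <- smooth_signal(p, 3L)
  expect_equal(sm$s1, c(0, 0, 0, 0, 0))
  expect_equal(sm[, c("probe", "start", "end")], p[, c("probe", "start", "end")])
  expect_error(smooth_signal(p, 2L), "odd")
  expect_error(smooth_signal(p, 0L), "odd")
})

test_that("smoothing matches the brute-force sliding median per strand", {
  set.seed(31)
  n <- 201
  p <- rbind(make_probe_df(seq(1, by = 20, length.out = n), rnorm(n), "+"),
             make_probe_df(seq(1, by = 20, length.out = n), rnorm(n), "-"))
  p$probe <- sprintf("p%04d", seq_len(nrow(p)))
  for (w in c(3L, 5L, 9L)) {
    sm <- smooth_signal(p, w)
    for (str in c("+", "-")) {
      idx <- p$strand == str
      expect_equal(sm$s1[idx], bf_running_median(p$s1[idx], w),
                   tolerance = 1e-12)
    }
  }
})

test_that("aggregation implements the strict containment and median rules", {
  ann <- data.frame(feature = "f1", start = 100L, end = 300L, strand = "+",
                    operon = "f1", operon_pos = 1L, stringsAsFactors = FALSE)
  class(ann) <- c("genome_annotation", "data.frame")
  p <- make_probe_df(c(110L, 150L, 200L, 95L, 292L), c(2, 4, 6, 100, 100),
                     len = 10L)
  # probe [95,104] overlaps the feature start: excluded; [292,301] crosses
  # the end: excluded
  expect_warning(res <- aggregate_features(p, ann), NA)
  expect_equal(unname(res["f1", "s1"]), 4)
  # non-unique probes are never eligible
  p$unique_match[3] <- FALSE
  res2 <- aggregate_features(p, ann)
  expect_equal(unname(res2["f1", "s1"]), 3)
  # opposite-strand probes are never eligible
  p$strand <- "-"
  expect_message(res3 <- aggregate_features(p, ann), "masked")
  expect_true(is.na(res3["f1", "s1"]))
  expect_equal(attr(res3, "masked"), "f1")
})

test_that("aggregation equals the brute-force recomputation on simulated data", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  design <- make_design(cfg)
  probes <- simulate_probe_signals(ann, truth, design, cfg)
  res <- suppressMessages(aggregate_features(probes, ann))
  for (col in c("WT_1", "sigW_2", "prsW_3")) {
    bf <- bf_aggregate(probes, ann, col)
    expect_equal(unname(res[, col]), unname(bf[rownames(res)]),
                 tolerance = 1e-12)
  }
  # invariance to probe order
  perm <- sample(nrow(probes))
  res_perm <- suppressMessages(aggregate_features(probes[perm, ], ann))
  expect_equal(res, res_perm)
})

test_that("zero-noise aggregation recovers the planted values exactly", {
  cfg <- small_config(noise_sd = 0, array_distortion = 0,
                      nonunique_fraction = 0, regulon_fraction = 0.4,
                      antisense_fraction = 0)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  design <- make_design(cfg)
  probes <- simulate_probe_signals(ann, truth, design, cfg)
  res <- suppressMessages(aggregate_features(smooth_signal(probes, 3L), ann))
  ok <- !is.na(res[, 1])
  m <- match(rownames(res)[ok], truth$feature)
  expect_equal(unname(res[ok, "WT_1"]), truth$baseline[m])
  expect_equal(unname(res[ok, "sigW_1"]),
               truth$baseline[m] + truth$effect_sigW[m])
})

test_that("the median aggregate resists corruption of a minority of probes", {
  ann <- data.frame(feature = "f1", start = 1L, end = 1000L, strand = "+",
                    operon = "f1", operon_pos = 1L, stringsAsFactors = FALSE)
  class(ann) <- c("genome_annotation", "data.frame")
  set.seed(8)
  starts <- seq(10L, 900L, by = 30L)
  p <- make_probe_df(starts, rep(5, length(starts)))
  before <- aggregate_features(p, ann)["f1", "s1"]
  k <- floor(length(starts) / 2) - 1L          # strictly fewer than half
  p$s1[sample(length(starts), k)] <- 1e6
  after <- aggregate_features(p, ann)["f1", "s1"]
  expect_equal(after, before)
})
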