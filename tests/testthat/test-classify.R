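fx <- regulon_fixtures()
ev_fix <- fixture_evidence(fx)

test_that("candidate selection applies strict thresholds", {
  ct <- data.frame(feature = c("a", "b", "c", "d", "e"),
                   contrast = "sigW/WT",
                   effect = c(-0.40, -0.41, 0.40, 0.41, -2),
                   p = c(0.01, 0.01, 0.01, 0.01, 0.05),
                   stringsAsFactors = FALSE)
  cand <- select_candidates(ct)
  expect_equal(cand$down, "b")      # -0.40 exactly and p = 0.05 are excluded
  expect_equal(cand$up, "d")
  expect_error(select_candidates(ct, contrast_name = "rasP/WT"), "not in table")
})

test_that("published table rows land in the documented candidate sets", {
  ct <- fixture_contrast(fx)
  cand <- select_candidates(ct)
  expect_true("rsiW" %in% cand$down)     # effect -6.84
  expect_true("ybbK" %in% cand$up)       # effect 3.07
  expect_false("yxzE" %in% cand$down)    # p = 0.08 misses the cut
  expect_false("S1489" %in% cand$down)   # effect -0.31 misses the cut
})

test_that("amplitude groups split at the boundary, boundary to group 1", {
  ev <- data.frame(feature = c("yfhL", "S659", "ywaC", "edge", "null"),
                   effect = c(-2.52, -0.94, 0.06, -1.5, 0.0),
                   p = c(0.01, 0.01, 0.5, 0.01, 0.9),
                   prior_regulon = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(assign_group(ev), c("1", "2", "3", "1", "none"))
})

test_that("the rule cascade reproduces the worked examples", {
  calls <- classify_regulon(ev_fix)
  call_of <- setNames(calls$conclusion, calls$feature)
  expect_equal(call_of[["yjoB"]], "core")          # down + reference cluster
  expect_equal(call_of[["pspA"]], "secondary")     # down + salt, other cluster
  expect_equal(call_of[["mtlA"]], "background")    # down, no salt, no motif
  expect_equal(call_of[["yxjH"]], "read_through")  # downstream of a core unit
  expect_equal(call_of[["yxzE"]], "core")          # borderline rescue p = 0.08
  expect_equal(call_of[["S1489"]], "core")         # co-transcribed companion
  expect_equal(call_of[["bscR"]], "other_sigma")
  expect_equal(call_of[["ywbO"]], "not_regulated")
})

test_that("every feature gets exactly one conclusion; down and up are disjoint", {
  calls <- classify_regulon(ev_fix)
  expect_equal(nrow(calls), nrow(ev_fix))
  expect_true(all(calls$conclusion %in%
                    c("core", "secondary", "read_through", "background",
                      "other_sigma", "not_regulated")))
  expect_false(any(calls$down_candidate & calls$up_candidate))
  # group invariants
  g1 <- calls$group == "1"
  expect_true(all(calls$effect[g1] <= -1.5 & calls$p[g1] < 0.05))
  g2 <- calls$group == "2"
  expect_true(all(calls$effect[g2] > -1.5 & calls$effect[g2] < -0.4 &
                    calls$p[g2] < 0.05))
  g3 <- calls$group == "3"
  expect_true(all(calls$prior_regulon[g3] & !calls$down_candidate[g3]))
  # the cascade is deterministic: rerunning gives identical output
  expect_identical(calls, classify_regulon(ev_fix))
})

test_that("the rescue rule admits only reference-cluster borderline features", {
  ev <- data.frame(feature = c("bord", "weak_eff", "off_cluster"),
                   effect = c(-0.45, -0.30, -0.45),
                   p = c(0.08, 0.08, 0.08),
                   in_reference_cluster = c(TRUE, TRUE, FALSE),
                   salt_induced = FALSE, motif = TRUE, prior_regulon = TRUE,
                   stringsAsFactors = FALSE)
  calls <- classify_regulon(ev)
  expect_equal(calls$conclusion,
               c("core", "not_regulated", "not_regulated"))
  # tightening rescue_p shuts the door
  calls2 <- classify_regulon(ev, rescue_p = 0.05)
  expect_equal(calls2$conclusion[1], "not_regulated")
})

test_that("operon summaries reproduce the published compositions", {
  calls <- classify_regulon(ev_fix)
  ops <- summarize_operons(calls)
  comp <- setNames(ops$composition, ops$operon)
  expect_equal(comp[["yuaF-yuaG-yuaI"]], "group1_only")
  expect_equal(comp[["yknW-yknX-yknY-yknZ"]], "group2_only")
  expect_equal(comp[["ybfO-ybfP-S89"]], "mixed")
  expect_true(ops$group2_at_end[ops$operon == "ybfO-ybfP-S89"])
  # operons holding only background members never appear
  expect_false("mtlA-mtlF-mtlD" %in% ops$operon)
  # the rescued-only unit is present but composition-excluded
  expect_equal(comp[["yxzE-S1489"]], "excluded")
})

test_that("opposite-strand flags find planted antisense partners and only them", {
  cfg <- small_config(antisense_fraction = 0.3)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  regulon <- truth$feature[truth$membership == "core"]
  partners <- ann$feature[!is.na(ann$antisense_of) &
                            ann$antisense_of %in% regulon]
  far <- setdiff(ann$feature[ann$type == "gene" & !ann$regulon_operon],
                 c(regulon, ann$antisense_of))
  up_set <- c(partners, far[1:5])
  flags <- flag_opposite_strand(up_set, regulon, ann)
  expect_named(flags, up_set)
  expect_true(all(flags[partners]))
  # brute-force interval check over all pairs agrees exactly
  expected <- vapply(up_set, function(u) {
    i <- match(u, ann$feature)
    any(ann$feature %in% regulon & ann$strand != ann$strand[i] &
          ann$start <= ann$end[i] + 100 & ann$end >= ann$start[i] - 100)
  }, logical(1))
  expect_equal(unname(flags), unname(expected))
})
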