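test_that("classify_segment separates crossings from hairpins", {
  b <- make_helix_bundle(2, seed = 6)
  for (i in seq_len(nrow(b$truth)))
    expect_equal(classify_segment(b$placement, b$truth[i, ]),
                 "transmembrane")
  h <- make_hairpin(depth = 12, seed = 6)
  expect_equal(classify_segment(h$placement, h$segment), "re-entrant")
  # a looser distance bound flips the same hairpin to transmembrane:
  # penetration 12 of 30 A leaves ~18 A to the far boundary
  expect_equal(classify_segment(h$placement, h$segment,
                                aftm_config(boundary_dist_max = 20)),
               "transmembrane")
  expect_error(classify_segment(b$placement, residue_range(5000, 5100)),
               "no residues")
})

test_that("classify_segment is invariant under joint rigid transforms", {
  set.seed(61)
  b <- make_helix_bundle(3, seed = 7)
  h <- make_hairpin(depth = 10, seed = 7)
  for (rep in 1:5) {
    tr <- random_rigid_transform()
    bt <- transform_placement(b$placement, tr$rotation, tr$translation)
    ht <- transform_placement(h$placement, tr$rotation, tr$translation)
    for (i in seq_len(nrow(b$truth)))
      expect_equal(classify_segment(bt, b$truth[i, ]), "transmembrane")
    expect_equal(classify_segment(ht, h$segment), "re-entrant")
  }
})

tm_pair <- function(starts, ends, orient = c("up", "up")) {
  tms_segments(starts, ends,
               entry = ifelse(orient == "up", "side1", "side2"),
               exit = ifelse(orient == "up", "side2", "side1"),
               kind = "transmembrane", source = "t")
}

test_that("merge_segments joins same-orientation segments split by < 10", {
  m <- merge_segments(tm_pair(c(100, 121), c(115, 134)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 134L))
  # gap 12: unchanged
  m2 <- merge_segments(tm_pair(c(100, 128), c(115, 140)))
  expect_equal(nrow(m2), 2L)
  # gap 5 but opposite orientation: unchanged
  m3 <- merge_segments(tm_pair(c(100, 121), c(115, 134), c("up", "down")))
  expect_equal(nrow(m3), 2L)
  # chain of three merges to one
  m4 <- merge_segments(tm_pair(c(10, 30, 50), c(24, 44, 64),
                               rep("up", 3)))
  expect_equal(nrow(m4), 1L)
  expect_equal(c(m4$start, m4$end), c(10L, 64L))
})

test_that("merge_segments is idempotent and matches the fixpoint oracle", {
  set.seed(71)
  for (i in 1:60) {
    segs <- random_segment_list()
    got <- merge_segments(segs)
    expect_equal(as.data.frame(merge_segments(got)), as.data.frame(got))
    want <- oracle_merge(segs)
    expect_equal(as.data.frame(got)[, c("start", "end", "entry", "exit")],
                 want[, c("start", "end", "entry", "exit")])
  }
})

test_that("recover_missing inserts the center-residue segment", {
  b <- make_helix_bundle(4, seed = 8)
  dropped <- b$truth[2, ]
  p <- make_placement(b, drop_indices = 2L)
  segs <- as.data.frame(p$raw_segments)
  segs$kind <- "transmembrane"
  out <- recover_missing(p, restore_segments(segs))
  expect_equal(nrow(out), 4L)
  ins <- out[2, ]
  # oracle: recompute every gap residue's |d1 - d2| from raw coordinates
  gap_res <- (segs$end[[1]] + 1L):(segs$start[[2]] - 1L)
  a <- p$model$atoms
  a <- a[a$resno %in% gap_res & a$atom %in% c("N", "CA", "C", "O"), ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d1 <- tapply(boundary_distance(xyz, p$geometry, 1), a$resno, min)
  d2 <- tapply(boundary_distance(xyz, p$geometry, 2), a$resno, min)
  center <- as.integer(names(d1))[which.min(abs(d1 - d2))]
  expect_equal(c(ins$start, ins$end), c(center - 5L, center + 5L))
  # inserted orientation is the reverse of the flanks
  expect_equal(ins$entry, segs$exit[[1]])
  expect_equal(ins$exit, segs$entry[[1]])
  # overlap with the withheld truth
  expect_gte(overlap_len(c(ins$start, ins$end),
                         c(dropped$start, dropped$end)), 10L)
})

test_that("recovery requires same orientation and a gap of at least 15", {
  b <- make_helix_bundle(4, seed = 8)
  # opposite orientations: no insertion
  opp <- tm_pair(c(6, 34), c(25, 53), c("up", "down"))
  expect_equal(nrow(recover_missing(b$placement, opp)), 2L)
  # same orientation, gap 14: below the bound, no insertion
  near <- tm_pair(c(6, 40), c(25, 53), c("up", "up"))
  expect_equal(nrow(recover_missing(b$placement, near)), 2L)
  # same orientation, gap 15: qualifies
  at <- tm_pair(c(6, 41), c(25, 53), c("up", "up"))
  expect_equal(nrow(recover_missing(b$placement, at)), 3L)
})

test_that("recovered segments are clipped away from their flanks", {
  b <- make_helix_bundle(4, seed = 8)
  out <- recover_missing(b$placement,
                         tm_pair(c(6, 41), c(25, 53), c("up", "up")))
  expect_silent(aftm:::assert_sorted_nonoverlapping(as.data.frame(out)))
  ins <- out[2, ]
  expect_lte(ins$end - ins$start + 1L, 11L)
})

test_that("recovery warns and skips gaps without coordinates", {
  b <- make_helix_bundle(2, seed = 9)
  # segments placed beyond the model numbering: the gap has no residues
  far <- tm_pair(c(500, 600), c(520, 620), c("up", "up"))
  expect_warning(out <- recover_missing(b$placement, far),
                 "recovery skipped")
  expect_equal(nrow(out), 2L)
})

test_that("call_tms composes classification, merging and recovery", {
  b <- make_helix_bundle(4, seed = 10)
  empty <- membrane_placement(b$model, b$geometry, tms_segments())
  res0 <- call_tms(empty)
  expect_equal(nrow(res0$tms), 0L)
  res <- call_tms(b$placement)
  expect_equal(nrow(res$tms), 4L)
  expect_equal(res$tms$entry, c("side1", "side2", "side1", "side2"))
  # one crossing dropped: recovered with >= 10 residue overlap to truth
  p <- make_placement(b, drop_indices = 3L)
  res2 <- call_tms(p)
  expect_equal(nrow(res2$tms), 4L)
  rec <- res2$tms[res2$tms$provenance == "recovered", ]
  expect_equal(nrow(rec), 1L)
  expect_gte(overlap_len(c(rec$start, rec$end),
                         c(b$truth$start[[3]], b$truth$end[[3]])), 10L)
  # re-entrant segments are excluded from the TMS track but reported
  h <- make_hairpin(depth = 12, seed = 10)
  res3 <- call_tms(h$placement)
  expect_equal(nrow(res3$tms), 0L)
  expect_equal(nrow(res3$reentrant), 1L)
  expect_equal(res3$reentrant$kind, "re-entrant")
})

test_that("combine_full_domain prefers full-model boundaries", {
  full <- tm_pair(10, 30, "up")
  dom <- tm_pair(c(12, 60), c(32, 80), c("up", "down"))
  out <- combine_full_domain(full, list(dom))
  expect_equal(out$start, c(10L, 60L))
  expect_equal(out$end, c(30L, 80L))
  out2 <- combine_full_domain(tms_segments(), list(tm_pair(60, 80, "up")))
  expect_equal(c(out2$start, out2$end), c(60L, 80L))
  out3 <- combine_full_domain(full, list())
  expect_equal(as.data.frame(out3), as.data.frame(full))
  # overlapping survivors (overlap < 10) merge to their union span
  out4 <- combine_full_domain(full, list(tm_pair(25, 50, "up")))
  expect_equal(nrow(out4), 1L)
  expect_equal(c(out4$start, out4$end), c(10L, 50L))
})
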