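test_that("overlap_len follows closed-interval arithmetic", {
  expect_equal(overlap_len(residue_range(10, 30), residue_range(21, 45)), 10L)
  expect_equal(overlap_len(residue_range(10, 30), residue_range(31, 45)), 0L)
  expect_equal(overlap_len(residue_range(10, 30), residue_range(10, 30)), 21L)
  expect_equal(overlap_len(c(1, 5), c(100, 120)), 0L)
})

test_that("overlap_len is symmetric", {
  set.seed(11)
  for (i in 1:50) {
    a <- sort(sample.int(200L, 2L))
    b <- sort(sample.int(200L, 2L))
    expect_identical(overlap_len(a, b), overlap_len(b, a))
  }
})

test_that("gap_len counts residues strictly between ordered ranges", {
  expect_equal(gap_len(residue_range(100, 115), residue_range(121, 134)), 5L)
  expect_equal(gap_len(residue_range(50, 70), residue_range(100, 120)), 29L)
  expect_equal(gap_len(residue_range(10, 20), residue_range(21, 30)), 0L)
  expect_error(gap_len(residue_range(10, 30), residue_range(21, 45)),
               "overlap")
  expect_error(gap_len(residue_range(50, 70), residue_range(10, 20)),
               "overlap|order")
})

test_that("residue ranges enforce their invariants", {
  expect_error(residue_range(0, 5), ">= 1")
  expect_error(residue_range(10, 9), ">= start")
  expect_equal(range_length(residue_range(7, 7)), 1L)
})

test_that("boundary_distance handles planar and spherical geometry", {
  gp <- membrane_planar(c(0, 0, 1), c(0, 30))
  expect_equal(boundary_distance(c(3, 4, 7), gp, 1), 7)
  expect_equal(boundary_distance(c(3, 4, 7), gp, 2), 23)
  expect_equal(boundary_distance(c(1, 2, 0), gp, 1), 0)
  gs <- membrane_spherical(c(0, 0, 0), c(100, 130))
  p <- 93 / sqrt(3) * c(1, 1, 1)  # at distance 93 from the origin
  expect_equal(boundary_distance(p, gs, 1), 7, tolerance = 1e-12)
  expect_error(membrane_planar(c(0, 0, 0), c(0, 30)), "non-zero")
  expect_error(membrane_spherical(c(0, 0, 0), c(120, 100)), "r1 < r2")
  expect_error(membrane_planar(c(0, 0, 1), c(30, 30)), "o1 < o2")
})

test_that("non-unit normals are normalized without moving the planes", {
  g1 <- membrane_planar(c(0, 0, 2), c(0, 60))  # same planes as z in [0, 30]
  g2 <- membrane_planar(c(0, 0, 1), c(0, 30))
  p <- c(5, -2, 13)
  expect_equal(boundary_distance(p, g1, 1), boundary_distance(p, g2, 1))
  expect_equal(boundary_distance(p, g1, 2), boundary_distance(p, g2, 2))
})

test_that("boundary_distance is invariant under joint rigid transforms", {
  set.seed(21)
  geoms <- list(membrane_planar(c(0, 0, 1), c(-12, 18)),
                membrane_spherical(c(5, -3, 2), c(80, 110)))
  for (g in geoms) {
    for (rep in 1:20) {
      tr <- random_rigid_transform()
      p <- stats::rnorm(3L, sd = 40)
      p2 <- drop(tr$rotation %*% p) + tr$translation
      g2 <- transform_geometry(g, tr$rotation, tr$translation)
      for (which in 1:2)
        expect_equal(boundary_distance(p2, g2, which),
                     boundary_distance(p, g, which), tolerance = 1e-6)
    }
  }
})

test_that("a point between the boundary planes is close to both", {
  set.seed(31)
  g <- membrane_planar(c(0, 0, 1), c(0, 30))
  for (i in 1:50) {
    p <- c(stats::rnorm(2, sd = 30), stats::runif(1, 0, 30))
    expect_lte(boundary_distance(p, g, 1), 30)
    expect_lte(boundary_distance(p, g, 2), 30)
  }
})

test_that("segment tables enforce orientation/kind invariants", {
  expect_error(tms_segments(10, 30, entry = "side1", exit = "side1",
                            kind = "transmembrane"),
               "opposite")
  expect_error(tms_segments(10, 30, entry = "side1", exit = "side2",
                            kind = "re-entrant"),
               "same side")
  expect_error(tms_segments(10, 5), "bounds")
  ok <- tms_segments(c(10, 40), c(30, 60), entry = c("side1", "side2"),
                     exit = c("side2", "side1"), kind = "transmembrane")
  expect_s3_class(ok, "tms_segments")
})

test_that("structure models keep strictly ordered numbering and valid pLDDT", {
  atoms <- data.frame(resno = c(2, 2, 1, 1), atom = c("N", "CA", "N", "CA"),
                      x = 0, y = 0, z = 0, plddt = c(80, 80, 90, 90))
  m <- structure_model("P", atoms)
  expect_identical(residue_numbers(m), c(1L, 2L))
  expect_equal(unname(residue_plddt(m)), c(90, 80))
  atoms$plddt <- c(80, 80, 90, 101)
  expect_error(structure_model("P", atoms), "\\[0, 100\\]")
})

test_that("annotation sets deduplicate and sort", {
  ann <- annotation_set(c("P2", "P1", "P1", "P1"), c("A", "U", "A", "A"),
                        c(5L, 12L, 10L, 10L), c(25L, 33L, 30L, 30L))
  expect_equal(nrow(ann), 3L)
  expect_identical(ann$protein, c("P1", "P1", "P2"))
  expect_equal(annotation_ranges(ann, "P1", "A"),
               data.frame(start = 10L, end = 30L))
  expect_equal(nrow(annotation_ranges(ann, "P9", "A")), 0L)
})

test_that("config validates thresholds", {
  expect_error(aftm_config(ratio_small = 5, ratio_big = 10), "ratio_small")
  expect_error(aftm_config(merge_gap_max = 0), "positive")
  cfg <- aftm_config(boundary_dist_max = 20)
  expect_equal(cfg$boundary_dist_max, 20)
  expect_equal(aftm_config()$pae_low_threshold, 12)
})
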