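mk_hit <- function(query = "Q1", subject = "S1", identity = 99,
                   qstart = 101, qend = 300, sstart = 1, send = 200,
                   qseq = NULL, sseq = NULL) {
  df <- data.frame(query = query, subject = subject, identity = identity,
                   length = send - sstart + 1L, mismatches = 0L, gapopen = 0L,
                   qstart = qstart, qend = qend, sstart = sstart, send = send,
                   evalue = 0, bitscore = 500, stringsAsFactors = FALSE)
  if (!is.null(qseq)) {
    df$qseq <- qseq
    df$sseq <- sseq
  }
  class(df) <- c("alignment_hits", "data.frame")
  df
}

test_that("filter_hits keeps identity strictly above the bound", {
  hits <- rbind(mk_hit(identity = 96.5), mk_hit(identity = 95.0),
                mk_hit(identity = 99.1))
  class(hits) <- c("alignment_hits", "data.frame")
  kept <- filter_hits(hits)
  expect_equal(kept$identity, c(96.5, 99.1))
  expect_equal(nrow(filter_hits(hits[0, ])), 0L)
})

test_that("offset projection maps subject ranges onto the query", {
  hit <- mk_hit(qstart = 101, qend = 300, sstart = 1, send = 200)
  pr <- project_range(hit, residue_range(5, 25))
  expect_equal(unname(unclass(pr)), c(105L, 125L))
  # no overlap with the aligned subject span
  expect_null(project_range(mk_hit(sstart = 10, send = 200, qstart = 101,
                                   qend = 291),
                            residue_range(1, 4)))
  # partial overlap is clipped, not discarded
  pr2 <- project_range(mk_hit(sstart = 10, send = 200, qstart = 101,
                              qend = 291),
                       residue_range(5, 15))
  expect_equal(unname(unclass(pr2)), c(101L, 106L))
  # length-mismatched hit without aligned strings is an error
  expect_error(project_range(mk_hit(qend = 298), residue_range(5, 25)),
               "aligned sequences")
})

test_that("gap-aware projection walks alignment columns", {
  # 2-column insertion in the subject (gaps in the query) before the range:
  # query coordinates shift by -2 relative to the naive offset
  hit <- mk_hit(qstart = 101, qend = 298, sstart = 1, send = 200,
                qseq = paste0(strrep("A", 10), "--", strrep("A", 188)),
                sseq = strrep("C", 200))
  pr <- project_range(hit, residue_range(15, 25))
  expect_equal(unname(unclass(pr)), c(113L, 123L))
  # oracle: per-column walk over the constructed alignment strings
  walk <- function(hit, s_range) {
    q <- strsplit(hit$qseq, "")[[1]]
    s <- strsplit(hit$sseq, "")[[1]]
    qp <- hit$qstart - 1L; sp <- hit$sstart - 1L
    qs <- integer()
    for (c in seq_along(q)) {
      if (q[c] != "-") qp <- qp + 1L
      if (s[c] != "-") sp <- sp + 1L
      if (q[c] != "-" && s[c] != "-" && sp >= s_range[1] && sp <= s_range[2])
        qs <- c(qs, qp)
    }
    c(min(qs), max(qs))
  }
  expect_equal(unname(unclass(pr)), walk(hit, c(15, 25)))
  # insertion in the query (gaps in the subject) inside the range widens it
  hit2 <- mk_hit(qstart = 1, qend = 203, sstart = 1, send = 200,
                 qseq = strrep("A", 203),
                 sseq = paste0(strrep("C", 20), "---", strrep("C", 180)))
  pr2 <- project_range(hit2, residue_range(15, 30))
  expect_equal(unname(unclass(pr2)), walk(hit2, c(15, 30)))
})

test_that("cluster_ranges implements single-linkage overlap clustering", {
  # [21,45] and [40,60] overlap by only 6, so they do not chain
  cl <- cluster_ranges(data.frame(start = c(10, 21, 40, 100),
                                  end = c(30, 45, 60, 120)))
  expect_equal(length(cl), 3L)
  expect_equal(cl[[1]], data.frame(start = c(10L, 21L), end = c(30L, 45L)))
  expect_equal(cl[[2]], data.frame(start = 40L, end = 60L))
  # a true chain: consecutive overlaps of exactly 10 link three ranges
  chain <- data.frame(start = c(10, 21, 32), end = c(30, 41, 52))
  expect_equal(length(cluster_ranges(chain)), 1L)
  expect_equal(length(cluster_ranges(data.frame(start = 7, end = 29))), 1L)
  # overlap 9: two singletons
  expect_equal(length(cluster_ranges(data.frame(start = c(10, 22),
                                                end = c(30, 45)))), 2L)
  expect_equal(length(cluster_ranges(data.frame(start = integer(),
                                                end = integer()))), 0L)
})

test_that("cluster_ranges matches the transitive-closure oracle", {
  set.seed(81)
  for (i in 1:40) {
    n <- sample(0:12, 1L)
    df <- data.frame(start = sample.int(150L, n, replace = TRUE))
    df$end <- df$start + sample.int(40L, n, replace = TRUE)
    got <- cluster_ranges(df)
    want <- oracle_cluster(df)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      want_df <- df[want[[k]], , drop = FALSE]
      expect_setequal(paste(got[[k]]$start, got[[k]]$end),
                      paste(want_df$start, want_df$end))
    }
  }
})

test_that("consensus_range takes floored medians", {
  expect_equal(unname(unclass(consensus_range(
    data.frame(start = c(10, 12, 15), end = c(30, 33, 36))))), c(12L, 33L))
  expect_equal(unname(unclass(consensus_range(
    data.frame(start = c(10, 13), end = c(30, 33))))), c(11L, 31L))
  expect_equal(unname(unclass(consensus_range(
    data.frame(start = 7, end = 29)))), c(7L, 29L))
  expect_error(consensus_range(data.frame(start = integer(),
                                          end = integer())), "empty")
})

test_that("consensus coordinates stay inside the cluster envelope", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(1:8, 1L)
    df <- data.frame(start = sample.int(100L, n, replace = TRUE))
    df$end <- df$start + sample.int(30L, n, replace = TRUE)
    cons <- consensus_range(df)
    expect_gte(cons[["start"]], min(df$start))
    expect_lte(cons[["start"]], max(df$start))
    expect_gte(cons[["end"]], min(df$end))
    expect_lte(cons[["end"]], max(df$end))
  }
})

test_that("build_reference runs filter, projection, clustering, consensus", {
  ref <- data.frame(subject = "S1", start = c(5, 60), end = c(25, 80))
  ann <- build_reference(ref, mk_hit(identity = 100), source = "PDBTM")
  expect_equal(as.data.frame(ann),
               data.frame(protein = "Q1", source = "PDBTM",
                          start = c(105L, 160L), end = c(125L, 180L)))
  # two subject chains mapping overlapping TMSs onto one query
  hits <- rbind(mk_hit(subject = "S1"),
                mk_hit(subject = "S2", qstart = 103, qend = 302))
  class(hits) <- c("alignment_hits", "data.frame")
  ref2 <- data.frame(subject = c("S1", "S2"), start = c(5, 5),
                     end = c(25, 25))
  ann2 <- build_reference(ref2, hits, source = "PDBTM")
  # projections [105,125] and [107,127] cluster; medians floor to [106,126]
  expect_equal(as.data.frame(ann2),
               data.frame(protein = "Q1", source = "PDBTM",
                          start = 106L, end = 126L))
  # nothing passes the filter
  expect_equal(nrow(build_reference(ref, mk_hit(identity = 90))), 0L)
})

test_that("build_reference is invariant to input row order", {
  set.seed(101)
  hits <- rbind(mk_hit(subject = "S1"),
                mk_hit(subject = "S2", qstart = 111, qend = 310),
                mk_hit(query = "Q2", subject = "S1", qstart = 51,
                       qend = 250))
  class(hits) <- c("alignment_hits", "data.frame")
  ref <- data.frame(subject = c("S1", "S1", "S2"), start = c(5, 100, 12),
                    end = c(25, 120, 30))
  base <- build_reference(ref, hits)
  for (i in 1:5) {
    perm_ref <- ref[sample.int(nrow(ref)), ]
    perm_hits <- hits[sample.int(nrow(hits)), ]
    class(perm_hits) <- c("alignment_hits", "data.frame")
    expect_identical(build_reference(perm_ref, perm_hits), base)
  }
})
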