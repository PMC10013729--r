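#' Filter alignment hits by sequence identity
#'
#' Keeps hits with percent identity strictly above `cfg$identity_min`
#' (default 95), so near-identical chains only are used to transfer TMS
#' annotations between proteins.
#'
#' @param hits An `alignment_hits` table from [read_hits()].
#' @param cfg An [aftm_config()].
#' @return The filtered `alignment_hits` table.
#' @export
filter_hits <- function(hits, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  out <- hits[hits$identity > cfg$identity_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a subject-sequence range onto the query through a hit
#'
#' Maps a TMS annotated on the subject (reference) sequence onto the query
#' protein. With aligned sequence strings present on the hit, the mapping
#' walks alignment columns and is gap-aware; otherwise the hit must be
#' length-matched (`qend - qstart == send - sstart`) and a plain offset
#' projection is used. Ranges extending past the aligned span are clipped;
#' a range with no overlap with the aligned subject span maps to nothing.
#'
#' @param hit One hit: a single-row `alignment_hits` data frame (or a list
#'   with the same fields).
#' @param subject_range [residue_range()] on the subject sequence.
#' @return A `residue_range` on the query, or `NULL` when no aligned subject
#'   position falls inside the range.
#' @export
project_range <- function(hit, subject_range) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    hit <- as.list(hit)
  }
  r <- as_residue_range(subject_range)
  s_lo <- max(r[["start"]], hit$sstart)
  s_hi <- min(r[["end"]], hit$send)
  if (s_lo > s_hi) return(NULL)
  has_seqs <- !is.null(hit$qseq) && !is.null(hit$sseq) &&
    !is.na(hit$qseq) && !is.na(hit$sseq) && nzchar(hit$qseq)
  if (!has_seqs) {
    if ((hit$qend - hit$qstart) != (hit$send - hit$sstart))
      stop("ungapped projection on a length-mismatched hit; ",
           "aligned sequences are required")
    off <- hit$qstart - hit$sstart
    return(residue_range(s_lo + off, s_hi + off))
  }
  qchr <- strsplit(hit$qseq, "", fixed = TRUE)[[1L]]
  schr <- strsplit(hit$sseq, "", fixed = TRUE)[[1L]]
  if (length(qchr) != length(schr))
    stop("aligned query/subject strings differ in length")
  qpos <- hit$qstart - 1L
  spos <- hit$sstart - 1L
  qhits <- integer()
  for (col in seq_along(qchr)) {
    qgap <- qchr[[col]] == "-"
    sgap <- schr[[col]] == "-"
    if (!qgap) qpos <- qpos + 1L
    if (!sgap) spos <- spos + 1L
    if (!sgap && !qgap && spos >= s_lo && spos <= s_hi)
      qhits <- c(qhits, qpos)
  }
  if (!length(qhits)) return(NULL)
  residue_range(min(qhits), max(qhits))
}

#' Single-linkage clustering of residue ranges
#'
#' Two ranges are linked when they overlap by at least
#' `cfg$match_overlap_min` residues; clusters are the connected components of
#' the link graph (so any chain of pairwise overlaps joins its members).
#' Clusters are ordered by their minimal start.
#'
#' @param ranges Data frame with `start`/`end` columns, or a list of
#'   [residue_range()]s.
#' @param cfg An [aftm_config()].
#' @return A list of data frames (one per cluster, each with `start`/`end`
#'   columns, members in input order).
#' @export
cluster_ranges <- function(ranges, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  df <- as_range_df(ranges)
  n <- nrow(df)
  if (!n) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ov <- min(df$end[[i]], df$end[[j]]) - max(df$start[[i]], df$start[[j]]) + 1L
      if (ov >= cfg$match_overlap_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[[rj]] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  groups <- split(seq_len(n), roots)
  clusters <- lapply(groups, function(idx) {
    out <- df[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  ord <- order(vapply(clusters, function(cl) min(cl$start), integer(1L)))
  unname(clusters[ord])
}

as_range_df <- function(ranges) {
  if (is.data.frame(ranges)) {
    df <- data.frame(start = as.integer(ranges$start),
                     end = as.integer(ranges$end))
  } else {
    rl <- normalize_range_list(ranges)
    df <- data.frame(start = vapply(rl, `[[`, integer(1L), "start"),
                     end = vapply(rl, `[[`, integer(1L), "end"))
  }
  if (nrow(df) && (any(df$start < 1L) || any(df$end < df$start)))
    stop("invalid ranges")
  df
}

#' Consensus range of a cluster
#'
#' The representative TMS of a cluster of mapped ranges: start and end are
#' the medians of the member starts and ends, rounded down to integers (so
#' for an even member count the lower midpoint average is floored).
#'
#' @param cluster Data frame with `start`/`end` columns, or a list of ranges;
#'   must be non-empty.
#' @return A [residue_range()].
#' @export
consensus_range <- function(cluster) {
  df <- as_range_df(cluster)
  if (!nrow(df)) stop("empty cluster")
  residue_range(floor(stats::median(df$start)), floor(stats::median(df$end)))
}

#' Transfer reference TMSs onto target proteins
#'
#' The full reference-mapping pipeline: alignment hits are filtered by
#' identity ([filter_hits()]); every reference TMS is projected through every
#' retained hit onto its query protein ([project_range()]); per query
#' protein, the projected ranges are clustered by single-linkage overlap
#' ([cluster_ranges()]) and each cluster is reduced to one consensus TMS
#' ([consensus_range()]).
#'
#' @param reference_tms Data frame with columns `subject`, `start`, `end`:
#'   TMS ranges on the reference (subject) sequences.
#' @param hits An `alignment_hits` table whose `subject` ids match
#'   `reference_tms$subject`.
#' @param cfg An [aftm_config()].
#' @param source Source label written into the output annotation set.
#' @return An [annotation_set()] of consensus TMSs keyed by query protein.
#' @export
build_reference <- function(reference_tms, hits, cfg = aftm_config(),
                            source = "reference") {
  cfg <- as_config(cfg)
  stopifnot(all(c("subject", "start", "end") %in% names(reference_tms)))
  hits <- filter_hits(hits, cfg)
  if (!nrow(hits) || !nrow(reference_tms)) return(annotation_set())
  projected <- list()
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, , drop = FALSE]
    tms <- reference_tms[reference_tms$subject == hit$subject, ,
                         drop = FALSE]
    for (k in seq_len(nrow(tms))) {
      pr <- project_range(hit, residue_range(tms$start[[k]], tms$end[[k]]))
      if (!is.null(pr))
        projected[[length(projected) + 1L]] <- data.frame(
          protein = hit$query, start = pr[["start"]], end = pr[["end"]],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(projected)) return(annotation_set())
  proj <- do.call(rbind, projected)
  proj <- proj[order(proj$protein, proj$start, proj$end), , drop = FALSE]
  rows <- list()
  for (pid in unique(proj$protein)) {
    sub <- proj[proj$protein == pid, c("start", "end"), drop = FALSE]
    for (cl in cluster_ranges(sub, cfg)) {
      cons <- consensus_range(cl)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = pid, source = source,
        start = cons[["start"]], end = cons[["end"]],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  annotation_set(df$protein, df$source, df$start, df$end)
}
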