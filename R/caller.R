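#' Classify a membrane-embedded segment as transmembrane or re-entrant
#'
#' The segment is extended by `cfg$tms_extension` residues on each side
#' (clipped to residues that exist in the model; trimmed numbering gaps are
#' simply skipped). Over all main-chain atoms (N, CA, C, O) of the extended
#' region, the minimum distance to each membrane boundary is computed. When
#' both minima are below `cfg$boundary_dist_max` Angstrom the region crosses
#' the membrane and is a transmembrane segment (TMS); otherwise it enters and
#' exits on the same side and is a re-entrant region, which is not reported
#' as a TMS.
#'
#' @param placement A [membrane_placement()].
#' @param seg A single segment: one row of a [tms_segments()] table or
#'   anything [residue_range()]-coercible.
#' @param cfg An [aftm_config()].
#' @return `"transmembrane"` or `"re-entrant"`.
#' @export
classify_segment <- function(placement, seg, cfg = aftm_config()) {
  stopifnot(inherits(placement, "membrane_placement"))
  cfg <- as_config(cfg)
  r <- as_residue_range(seg)
  ext <- c(r[["start"]] - cfg$tms_extension, r[["end"]] + cfg$tms_extension)
  mc <- main_chain_coords(placement$model)
  keep <- mc$resno >= ext[[1L]] & mc$resno <= ext[[2L]]
  if (!any(keep))
    stop("extended region [", ext[[1L]], ", ", ext[[2L]],
         "] contains no residues with coordinates")
  xyz <- mc$xyz[keep, , drop = FALSE]
  d1 <- min(boundary_distance(xyz, placement$geometry, 1L))
  d2 <- min(boundary_distance(xyz, placement$geometry, 2L))
  if (d1 < cfg$boundary_dist_max && d2 < cfg$boundary_dist_max)
    "transmembrane" else "re-entrant"
}

#' Merge broken same-orientation segments
#'
#' Placement tools sometimes report one kinked or broken helix as two
#' segments. Adjacent segments with identical (entry, exit) orientation
#' separated by fewer than `cfg$merge_gap_max` residues are merged into one
#' segment spanning both; merging repeats until no adjacent pair qualifies,
#' so the operation is idempotent.
#'
#' @param segments A [tms_segments()] table, sorted by start and
#'   non-overlapping.
#' @param cfg An [aftm_config()].
#' @return The merged `tms_segments` table.
#' @export
merge_segments <- function(segments, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  segments <- as.data.frame(segments)
  assert_sorted_nonoverlapping(segments)
  if (nrow(segments) < 2L) return(restore_segments(segments))
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(segments)) {
      a <- segments[i, ]
      b <- segments[i + 1L, ]
      same <- a$entry == b$entry && a$exit == b$exit
      gap <- b$start - a$end - 1L
      if (same && gap < cfg$merge_gap_max) {
        segments$end[i] <- b$end
        if ("provenance" %in% names(segments))
          segments$provenance[i] <- "merged"
        segments <- segments[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  rownames(segments) <- NULL
  restore_segments(segments)
}

restore_segments <- function(df) {
  class(df) <- c("tms_segments", "data.frame")
  df
}

# Per-residue minimum main-chain distances to both boundaries.
residue_boundary_distances <- function(placement, resnos) {
  mc <- main_chain_coords(placement$model, resnos)
  if (!length(mc$resno))
    return(data.frame(resno = integer(), d1 = numeric(), d2 = numeric()))
  d1 <- boundary_distance(mc$xyz, placement$geometry, 1L)
  d2 <- boundary_distance(mc$xyz, placement$geometry, 2L)
  data.frame(resno = sort(unique(mc$resno)),
             d1 = as.numeric(tapply(d1, mc$resno, min)),
             d2 = as.numeric(tapply(d2, mc$resno, min)))
}

#' Recover membrane crossings missed by the placement tool
#'
#' Two consecutive transmembrane segments with the same orientation imply an
#' even number of crossings between them; when the placement tool reports
#' none and they are separated by at least `cfg$missing_gap_min` residues,
#' one missed TMS is reconstructed. The gap residue closest to the membrane
#' center — the one with the smallest difference between its minimum
#' main-chain distances to the two boundaries (ties to the smaller residue
#' number) — becomes the center of an inserted segment extending
#' `cfg$missing_halfwidth` residues on each side, clipped so it overlaps
#' neither flanking segment. The inserted segment gets the reversed
#' orientation of its flanks. At most one segment is inserted per qualifying
#' gap; gaps whose residues all lack coordinates are skipped with a warning.
#'
#' @param placement A [membrane_placement()].
#' @param segments Sorted, merged [tms_segments()] table.
#' @param cfg An [aftm_config()].
#' @return `tms_segments` table with recovered segments inserted (sorted).
#' @export
recover_missing <- function(placement, segments, cfg = aftm_config()) {
  stopifnot(inherits(placement, "membrane_placement"))
  cfg <- as_config(cfg)
  segments <- as.data.frame(segments)
  assert_sorted_nonoverlapping(segments)
  inserted <- list()
  if (nrow(segments) >= 2L) {
    for (i in seq_len(nrow(segments) - 1L)) {
      a <- segments[i, ]
      b <- segments[i + 1L, ]
      if (!(a$entry == b$entry && a$exit == b$exit)) next
      gap <- b$start - a$end - 1L
      if (gap < cfg$missing_gap_min) next
      gap_res <- (a$end + 1L):(b$start - 1L)
      dists <- residue_boundary_distances(placement, gap_res)
      if (!nrow(dists)) {
        warning("gap ", a$end + 1L, "-", b$start - 1L,
                " has no residues with coordinates; recovery skipped")
        next
      }
      center <- dists$resno[[which.min(abs(dists$d1 - dists$d2))]]
      new <- a  # copy the flank row so extra columns are preserved
      new$start <- max(center - cfg$missing_halfwidth, a$end + 1L)
      new$end <- min(center + cfg$missing_halfwidth, b$start - 1L)
      new$entry <- a$exit
      new$exit <- a$entry
      new$kind <- "transmembrane"
      if ("provenance" %in% names(new)) new$provenance <- "recovered"
      inserted[[length(inserted) + 1L]] <- new
    }
  }
  if (length(inserted))
    segments <- rbind(segments, do.call(rbind, inserted))
  segments <- sort_segments(segments)
  rownames(segments) <- NULL
  restore_segments(segments)
}

#' Call final transmembrane segments from a membrane placement
#'
#' The full correction pipeline applied to the raw segments of one placement:
#' every raw segment is classified ([classify_segment()]); re-entrant regions
#' are set aside (reported separately, never as TMSs); the remaining
#' transmembrane segments are merged ([merge_segments()]) and missed
#' crossings recovered ([recover_missing()]). The result is deterministic.
#'
#' @param placement A [membrane_placement()].
#' @param cfg An [aftm_config()].
#' @param source Source label written on the output segments.
#' @return A list with elements `tms` (sorted `tms_segments`, kind
#'   `"transmembrane"`) and `reentrant` (kind `"re-entrant"`).
#' @export
call_tms <- function(placement, cfg = aftm_config(), source = "AFTM") {
  stopifnot(inherits(placement, "membrane_placement"))
  cfg <- as_config(cfg)
  raw <- as.data.frame(placement$raw_segments)
  if (!nrow(raw)) {
    return(list(tms = tms_segments(), reentrant = tms_segments()))
  }
  kinds <- vapply(seq_len(nrow(raw)), function(i)
    classify_segment(placement, raw[i, ], cfg), character(1L))
  re <- raw[kinds == "re-entrant", , drop = FALSE]
  tm <- raw[kinds == "transmembrane", , drop = FALSE]
  if (nrow(re)) {
    re$kind <- "re-entrant"
    re$exit <- re$entry  # same-side by definition; keep the reported entry
    re$source <- source
  }
  if (nrow(tm)) {
    tm$kind <- "transmembrane"
    tm$source <- source
    tm$provenance <- "raw"
    tm <- merge_segments(tm, cfg)
    tm <- recover_missing(placement, tm, cfg)
  }
  rownames(tm) <- rownames(re) <- NULL
  list(tms = restore_segments(tm), reentrant = restore_segments(re))
}

#' Combine full-model and per-domain TMS calls
#'
#' TMSs are called both on the trimmed full-length model and on each ordered
#' domain; the final annotation is their union. A domain-derived segment that
#' overlaps a full-model segment by at least `cfg$match_overlap_min` residues
#' is the same crossing seen twice, and the full-model boundaries are kept.
#' Any remaining overlapping survivors are merged to their union span.
#'
#' @param full [tms_segments()] from the full-model placement.
#' @param per_domain List of `tms_segments` tables, one per domain placement.
#' @param cfg An [aftm_config()].
#' @return Sorted, non-overlapping `tms_segments` table.
#' @export
combine_full_domain <- function(full, per_domain = list(),
                                cfg = aftm_config()) {
  cfg <- as_config(cfg)
  full <- as.data.frame(full)
  dom <- if (length(per_domain))
    do.call(rbind, lapply(per_domain, as.data.frame)) else
    as.data.frame(tms_segments())
  keep_dom <- rep(TRUE, nrow(dom))
  if (nrow(dom) && nrow(full)) {
    for (i in seq_len(nrow(dom))) {
      ov <- vapply(seq_len(nrow(full)), function(j)
        overlap_len(c(dom$start[[i]], dom$end[[i]]),
                    c(full$start[[j]], full$end[[j]])), integer(1L))
      if (any(ov >= cfg$match_overlap_min)) keep_dom[[i]] <- FALSE
    }
  }
  out <- rbind(full, dom[keep_dom, , drop = FALSE])
  if (!nrow(out)) return(tms_segments())
  out <- sort_segments(out)
  # merge any overlapping survivors to their union span
  i <- 1L
  while (i < nrow(out)) {
    if (out$start[[i + 1L]] <= out$end[[i]]) {
      out$end[[i]] <- max(out$end[[i]], out$end[[i + 1L]])
      out <- out[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  rownames(out) <- NULL
  restore_segments(out)
}
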