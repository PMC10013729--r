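#' Residue range
#'
#' A 1-based closed interval on a protein sequence, the unit of every
#' transmembrane-segment (TMS) annotation. Coordinates follow the UniProt
#' TRANSMEM convention: both endpoints are residue indices and both are
#' included, so the length of `[start, end]` is `end - start + 1`.
#'
#' @param start First residue index (>= 1).
#' @param end Last residue index (>= start).
#' @return A named integer vector of class `residue_range` with elements
#'   `start` and `end`.
#' @examples
#' r <- residue_range(10, 30)
#' range_length(r)  # 21
#' @export
residue_range <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing integers")
  if (start < 1L) stop("start must be >= 1")
  if (end < start) stop("end must be >= start")
  structure(c(start = start, end = end), class = "residue_range")
}

as_residue_range <- function(x) {
  if (inherits(x, "residue_range")) return(x)
  if (is.list(x) && all(c("start", "end") %in% names(x)))
    return(residue_range(x$start, x$end))
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single range")
    return(residue_range(x$start, x$end))
  }
  if (is.numeric(x) && length(x) == 2L) return(residue_range(x[[1L]], x[[2L]]))
  stop("cannot interpret object as a residue range")
}

#' @rdname residue_range
#' @param r A `residue_range` (or any object coercible to one).
#' @export
range_length <- function(r) {
  r <- as_residue_range(r)
  unname(r[["end"]] - r[["start"]] + 1L)
}

#' Overlap length of two residue ranges
#'
#' Number of residues shared by two closed intervals; 0 when they are
#' disjoint (adjacent ranges such as `[10,30]` and `[31,45]` do not overlap).
#'
#' @param a,b Residue ranges (see [residue_range()]); length-2 numeric
#'   vectors `c(start, end)` are accepted.
#' @return Integer overlap length, >= 0.
#' @examples
#' overlap_len(residue_range(10, 30), residue_range(21, 45))  # 10
#' @export
overlap_len <- function(a, b) {
  a <- as_residue_range(a)
  b <- as_residue_range(b)
  max(0L, min(a[["end"]], b[["end"]]) - max(a[["start"]], b[["start"]]) + 1L)
}

#' Gap length between two ordered residue ranges
#'
#' Number of residues strictly between `a` and `b`. Abutting ranges
#' (`a$end + 1 == b$start`) have gap 0. It is an error to call this on
#' overlapping or out-of-order ranges.
#'
#' @inheritParams overlap_len
#' @return Integer gap length, >= 0.
#' @export
gap_len <- function(a, b) {
  a <- as_residue_range(a)
  b <- as_residue_range(b)
  if (a[["end"]] >= b[["start"]])
    stop("ranges overlap or are out of order: a must end before b starts")
  unname(b[["start"]] - a[["end"]] - 1L)
}

# ---------------------------------------------------------------------------
# TMS segment tables
# ---------------------------------------------------------------------------

#' TMS segment tables
#'
#' Lists of membrane-embedded segments are represented as data frames with
#' columns `start`, `end` (1-based inclusive residue indices), `entry`,
#' `exit` (membrane side labels, `"side1"`/`"side2"`), `kind`
#' (`"transmembrane"`, `"re-entrant"` or `"raw"`) and `source` (free-text
#' provenance label). Side labels are abstract: for a planar membrane
#' `side1`/`side2` are below/above the slab; for a spherical membrane they
#' are inside/outside.
#'
#' @param start,end Integer vectors of segment bounds.
#' @param entry,exit Side labels, each `"side1"` or `"side2"`.
#' @param kind Segment kind; re-entrant segments must have `entry == exit`,
#'   transmembrane segments `entry != exit`.
#' @param source Free-text label recording where the segment came from.
#' @return A data frame of class `tms_segments`.
#' @export
tms_segments <- function(start = integer(), end = integer(),
                         entry = character(), exit = character(),
                         kind = character(), source = character()) {
  n <- max(length(start), length(end))
  if (length(kind) <= 1L) kind <- rep(if (length(kind)) kind else "raw", n)
  if (length(source) <= 1L) source <- rep(if (length(source)) source else "", n)
  if (length(entry) <= 1L) entry <- rep(if (length(entry)) entry else "side1", n)
  if (length(exit) <= 1L) exit <- rep(if (length(exit)) exit else "side2", n)
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   entry = as.character(entry), exit = as.character(exit),
                   kind = as.character(kind), source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_segments(df)
  class(df) <- c("tms_segments", "data.frame")
  df
}

validate_segments <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("invalid segment bounds: need 1 <= start <= end")
  bad_side <- !df$entry %in% c("side1", "side2") | !df$exit %in% c("side1", "side2")
  if (any(bad_side)) stop("entry/exit must be 'side1' or 'side2'")
  re <- df$kind == "re-entrant"
  if (any(re & df$entry != df$exit))
    stop("re-entrant segments must enter and exit on the same side")
  tm <- df$kind == "transmembrane"
  if (any(tm & df$entry == df$exit))
    stop("transmembrane segments must enter and exit on opposite sides")
  invisible(df)
}

sort_segments <- function(df) {
  df[order(df$start, df$end), , drop = FALSE]
}

assert_sorted_nonoverlapping <- function(df, what = "segments") {
  if (nrow(df) < 2L) return(invisible(df))
  if (any(diff(df$start) < 0L)) stop(what, " must be sorted by start")
  if (any(df$start[-1L] <= df$end[-nrow(df)]))
    stop(what, " must be non-overlapping")
  invisible(df)
}

# ---------------------------------------------------------------------------
# Membrane geometry
# ---------------------------------------------------------------------------

#' Membrane boundary geometry
#'
#' The two membrane boundary surfaces reported by a membrane-placement tool:
#' either two parallel planes (`n . x = o1` and `n . x = o2` with a unit
#' normal `n` and offsets `o1 < o2`, all in Angstrom) or two concentric
#' spheres (center plus radii `0 < r1 < r2`). Non-unit normals are
#' normalized, rescaling the offsets so the planes are unchanged.
#'
#' @param normal Length-3 numeric, the membrane normal (planar variant).
#' @param offsets Length-2 numeric, plane offsets with `offsets[1] < offsets[2]`.
#' @param center Length-3 numeric, sphere center (spherical variant).
#' @param radii Length-2 numeric, boundary radii with `0 < radii[1] < radii[2]`.
#' @return A list of class `membrane_geometry` with a `variant` field
#'   (`"planar"` or `"spherical"`).
#' @examples
#' g <- membrane_planar(c(0, 0, 1), c(0, 30))
#' boundary_distance(c(3, 4, 7), g, which = 1)  # 7
#' @export
membrane_planar <- function(normal, offsets) {
  normal <- as.numeric(normal)
  offsets <- as.numeric(offsets)
  if (length(normal) != 3L) stop("normal must have length 3")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("membrane normal must be non-zero")
  if (abs(nn - 1) > 1e-9) {
    normal <- normal / nn
    offsets <- offsets / nn
  }
  if (length(offsets) != 2L || !(offsets[2L] > offsets[1L]))
    stop("offsets must be two values with o1 < o2")
  structure(list(variant = "planar", normal = normal, offsets = offsets),
            class = "membrane_geometry")
}

#' @rdname membrane_planar
#' @export
membrane_spherical <- function(center, radii) {
  center <- as.numeric(center)
  radii <- as.numeric(radii)
  if (length(center) != 3L) stop("center must have length 3")
  if (length(radii) != 2L || radii[1L] <= 0 || radii[2L] <= radii[1L])
    stop("radii must satisfy 0 < r1 < r2")
  structure(list(variant = "spherical", center = center, radii = radii),
            class = "membrane_geometry")
}

#' Distance from a point to a membrane boundary
#'
#' For planar geometry, the perpendicular distance from the point to boundary
#' plane `which`; for spherical geometry, the absolute difference between the
#' point's distance from the center and boundary radius `which`.
#'
#' @param point Length-3 numeric coordinate (Angstrom), or an n x 3 matrix of
#'   coordinates (one distance per row is returned).
#' @param geometry A [membrane_planar()] / [membrane_spherical()] object.
#' @param which Boundary index, 1 or 2.
#' @return Non-negative distance(s) in Angstrom.
#' @export
boundary_distance <- function(point, geometry, which) {
  stopifnot(inherits(geometry, "membrane_geometry"), which %in% c(1, 2))
  pm <- if (is.matrix(point)) point else matrix(as.numeric(point), ncol = 3L)
  if (ncol(pm) != 3L) stop("point must be a 3-vector or an n x 3 matrix")
  if (geometry$variant == "planar") {
    abs(drop(pm %*% geometry$normal) - geometry$offsets[[which]])
  } else {
    d <- sqrt(rowSums(sweep(pm, 2L, geometry$center)^2))
    abs(d - geometry$radii[[which]])
  }
}

#' Membrane side of a point
#'
#' Labels which side of the membrane midplane (or mid-sphere) a point lies
#' on: `"side1"` below the midplane / inside the mid-radius, `"side2"`
#' otherwise.
#'
#' @inheritParams boundary_distance
#' @return `"side1"` or `"side2"` (vector for matrix input).
#' @export
membrane_side <- function(point, geometry) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  pm <- if (is.matrix(point)) point else matrix(as.numeric(point), ncol = 3L)
  if (geometry$variant == "planar") {
    mid <- mean(geometry$offsets)
    ifelse(drop(pm %*% geometry$normal) < mid, "side1", "side2")
  } else {
    mid <- mean(geometry$radii)
    d <- sqrt(rowSums(sweep(pm, 2L, geometry$center)^2))
    ifelse(d < mid, "side1", "side2")
  }
}

#' Apply a rigid transform to membrane geometry
#'
#' Rotates and translates the boundary geometry consistently with applying
#' `x -> R x + t` to all structure coordinates. For a plane `n . x = o`, the
#' transformed plane is `(R n) . x = o + (R n) . t`; spheres keep their radii
#' and move their center.
#'
#' @param geometry A `membrane_geometry`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric.
#' @return The transformed `membrane_geometry`.
#' @export
transform_geometry <- function(geometry, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (geometry$variant == "planar") {
    n2 <- drop(rotation %*% geometry$normal)
    membrane_planar(n2, geometry$offsets + sum(n2 * translation))
  } else {
    membrane_spherical(drop(rotation %*% geometry$center) + translation,
                       geometry$radii)
  }
}

# ---------------------------------------------------------------------------
# Structure models
# ---------------------------------------------------------------------------

#' Structure model
#'
#' An ordered set of residues with main-chain atom coordinates and a
#' per-residue confidence score (pLDDT on the 0-100 scale). Residue numbers
#' are strictly increasing but may have gaps (e.g. after trimming); they are
#' never renumbered, so segment coordinates from trimmed or extracted
#' sub-models remain directly comparable to full-model coordinates.
#'
#' @param protein_id Protein identifier.
#' @param atoms Data frame with columns `resno` (integer residue number),
#'   `atom` (atom name; main-chain atoms are `N`, `CA`, `C`, `O`),
#'   `x`, `y`, `z` (Angstrom) and `plddt` (0-100, constant within a residue).
#' @return A list of class `structure_model` with fields `protein_id` and
#'   `atoms` (sorted by residue number).
#' @export
structure_model <- function(protein_id, atoms) {
  required <- c("resno", "atom", "x", "y", "z", "plddt")
  if (!all(required %in% names(atoms)))
    stop("atoms must have columns: ", paste(required, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  if (nrow(atoms)) {
    if (any(atoms$plddt < 0 | atoms$plddt > 100))
      stop("pLDDT values must lie in [0, 100]")
    per_res <- tapply(atoms$plddt, atoms$resno, function(v) diff(range(v)))
    if (any(per_res > 1e-6))
      stop("pLDDT must be constant within a residue")
  }
  structure(list(protein_id = as.character(protein_id), atoms = atoms),
            class = "structure_model")
}

#' @rdname structure_model
#' @param model A `structure_model`.
#' @export
residue_numbers <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  unique(model$atoms$resno)
}

#' @rdname structure_model
#' @export
residue_plddt <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  keep <- !duplicated(a$resno)
  stats::setNames(a$plddt[keep], a$resno[keep])
}

#' @export
print.structure_model <- function(x, ...) {
  rn <- residue_numbers(x)
  cat(sprintf("structure_model '%s': %d residues (%s), %d atoms\n",
              x$protein_id, length(rn),
              if (length(rn)) paste0(min(rn), "-", max(rn)) else "empty",
              nrow(x$atoms)))
  invisible(x)
}

main_chain_coords <- function(model, resnos = NULL) {
  a <- model$atoms
  keep <- a$atom %in% c("N", "CA", "C", "O")
  if (!is.null(resnos)) keep <- keep & a$resno %in% resnos
  a <- a[keep, , drop = FALSE]
  list(resno = a$resno, xyz = as.matrix(a[, c("x", "y", "z")]))
}

#' Apply a rigid transform to a structure model
#'
#' @param model A `structure_model`.
#' @inheritParams transform_geometry
#' @return The transformed model (numbering and confidence unchanged).
#' @export
transform_model <- function(model, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(as.matrix(rotation))
  xyz <- sweep(xyz, 2L, as.numeric(translation), "+")
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

# ---------------------------------------------------------------------------
# Membrane placement
# ---------------------------------------------------------------------------

#' Membrane placement
#'
#' A structure model positioned in a membrane: boundary geometry plus the raw
#' membrane-embedded segments reported by the upstream placement tool
#' (PPM3-style), before any correction.
#'
#' @param model A [structure_model()].
#' @param geometry A `membrane_geometry`.
#' @param raw_segments A [tms_segments()] table (kind is forced to `"raw"`);
#'   must be sorted by start and non-overlapping.
#' @param membrane_type Free-text membrane type label.
#' @return A list of class `membrane_placement`.
#' @export
membrane_placement <- function(model, geometry, raw_segments,
                               membrane_type = "") {
  stopifnot(inherits(model, "structure_model"),
            inherits(geometry, "membrane_geometry"))
  raw_segments <- as.data.frame(raw_segments)
  if (nrow(raw_segments)) raw_segments$kind <- "raw"
  raw_segments <- sort_segments(raw_segments)
  assert_sorted_nonoverlapping(raw_segments, "raw segments")
  validate_segments(raw_segments)
  class(raw_segments) <- c("tms_segments", "data.frame")
  structure(list(model = model, geometry = geometry,
                 raw_segments = raw_segments,
                 membrane_type = as.character(membrane_type)),
            class = "membrane_placement")
}

#' @export
print.membrane_placement <- function(x, ...) {
  cat(sprintf("membrane_placement '%s': %s membrane, %d raw segments\n",
              x$model$protein_id, x$geometry$variant, nrow(x$raw_segments)))
  invisible(x)
}

#' Apply a rigid transform to a membrane placement
#'
#' Transforms structure and boundary geometry jointly, so all residue-to-
#' boundary distances (and hence every downstream TMS call) are preserved.
#'
#' @param placement A `membrane_placement`.
#' @inheritParams transform_geometry
#' @return The transformed placement.
#' @export
transform_placement <- function(placement, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(placement, "membrane_placement"))
  placement$model <- transform_model(placement$model, rotation, translation)
  placement$geometry <- transform_geometry(placement$geometry, rotation,
                                           translation)
  placement
}

# ---------------------------------------------------------------------------
# PAE matrices
# ---------------------------------------------------------------------------

#' Predicted-aligned-error matrix
#'
#' An L x L matrix of non-negative expected pair position errors (Angstrom)
#' from a structure predictor. The matrix may be asymmetric as exported;
#' consumers symmetrize with the elementwise minimum of the two directions.
#'
#' @param m Square numeric matrix with non-negative entries.
#' @return The matrix with class `pae_matrix`.
#' @export
pae_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("PAE matrix must be square")
  if (any(!is.finite(m)) || any(m < 0))
    stop("PAE entries must be finite and non-negative")
  class(m) <- c("pae_matrix", class(unclass(m)))
  m
}

pae_length <- function(pae) nrow(pae)

# ---------------------------------------------------------------------------
# Annotation sets
# ---------------------------------------------------------------------------

#' Annotation set
#'
#' Per-protein, per-source lists of TMS ranges: a data frame with columns
#' `protein`, `source`, `start`, `end`, kept sorted by protein, source and
#' start, with duplicate rows removed.
#'
#' @param protein,source Character vectors.
#' @param start,end Integer range bounds (1-based inclusive).
#' @return A data frame of class `annotation_set`.
#' @export
annotation_set <- function(protein = character(), source = character(),
                           start = integer(), end = integer()) {
  df <- data.frame(protein = as.character(protein),
                   source = as.character(source),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) && (any(df$start < 1L) || any(df$end < df$start)))
    stop("annotation ranges must satisfy 1 <= start <= end")
  df <- unique(df)
  df <- df[order(df$protein, df$source, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' @rdname annotation_set
#' @param ann An `annotation_set`.
#' @param protein_id,source_label Selectors; `NULL` keeps everything.
#' @return For `annotation_ranges()`: a data frame with `start`/`end` columns
#'   (possibly zero rows) for one (protein, source) pair.
#' @export
annotation_ranges <- function(ann, protein_id, source_label) {
  keep <- ann$protein == protein_id & ann$source == source_label
  out <- as.data.frame(ann)[keep, c("start", "end"), drop = FALSE]
  rownames(out) <- NULL
  out
}
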