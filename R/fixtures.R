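#' Synthetic helical-bundle fixture
#'
#' Generates an idealized multi-pass membrane protein: `n_helices` straight
#' helices crossing a planar membrane slab alternately up and down, connected
#' by loops outside the slab, with optional N/C-terminal tails. Helix
#' geometry uses the axial-rise idealization (1.5 Angstrom rise per residue
#' along the membrane normal, main-chain atoms placed on a helical curve);
#' this is sufficient for every boundary-distance computation the package
#' performs, with no claim of full backbone realism. Each crossing spans
#' `ceiling(thickness / 1.5)` residues and the returned truth table records
#' its range and orientation.
#'
#' @param n_helices Number of membrane crossings (>= 1).
#' @param thickness Membrane slab thickness d in Angstrom (> 0); the
#'   boundary planes are `z = 0` and `z = d`.
#' @param loop_len Residues per inter-helix loop (>= 1).
#' @param tail_len Residues in each terminal tail (>= 0).
#' @param helix_plddt,loop_plddt Confidence assigned inside helices and in
#'   loops/tails (0-100).
#' @param jitter_sd Standard deviation (Angstrom) of seeded Gaussian jitter
#'   added to every coordinate; keep well below the 10 Angstrom
#'   classification margin.
#' @param seed Integer seed making the fixture reproducible.
#' @param protein_id Identifier for the generated model.
#' @return A list with `model` ([structure_model()]), `geometry`
#'   ([membrane_planar()]), `truth` ([tms_segments()] of the planted
#'   crossings, kind `"transmembrane"`, source `"truth"`) and `placement`
#'   (a [membrane_placement()] whose raw segments equal the truth).
#' @export
make_helix_bundle <- function(n_helices = 4L, thickness = 30, loop_len = 8L,
                              tail_len = 5L, helix_plddt = 92,
                              loop_plddt = 85, jitter_sd = 0, seed = NULL,
                              protein_id = "bundle") {
  n_helices <- as.integer(n_helices)
  if (n_helices < 1L) stop("n_helices must be >= 1")
  if (thickness <= 0) stop("membrane thickness must be positive")
  if (loop_len < 1L && n_helices > 1L) stop("loop_len must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rise <- 1.5
  cross_len <- as.integer(ceiling(thickness / rise))
  geometry <- membrane_planar(c(0, 0, 1), c(0, thickness))
  helix_x <- function(i) (i - 1L) * 10
  res <- list()
  resno <- 0L
  add_residue <- function(x, y, z, plddt) {
    resno <<- resno + 1L
    # four main-chain atoms near the backbone position
    res[[length(res) + 1L]] <<- data.frame(
      resno = resno,
      atom = c("N", "CA", "C", "O"),
      x = x + c(-0.6, 0, 0.6, 0.9),
      y = y + c(0.3, 0, -0.3, 0.5),
      z = z + c(-0.4, 0, 0.4, 0.6),
      plddt = plddt, stringsAsFactors = FALSE)
  }
  # N-terminal tail below the membrane, approaching helix 1
  for (j in seq_len(tail_len))
    add_residue(helix_x(1L) - (tail_len - j + 1L) * 1.5, 3,
                -4 - (tail_len - j) * 1.2, loop_plddt)
  truth <- list()
  for (h in seq_len(n_helices)) {
    up <- h %% 2L == 1L
    start <- resno + 1L
    for (k in seq_len(cross_len)) {
      zfrac <- (k - 0.5) * rise
      z <- if (up) zfrac else thickness - zfrac
      theta <- k * 100 * pi / 180
      add_residue(helix_x(h) + 2.3 * cos(theta), 2.3 * sin(theta), z,
                  helix_plddt)
    }
    truth[[h]] <- data.frame(
      start = start, end = resno,
      entry = if (up) "side1" else "side2",
      exit = if (up) "side2" else "side1",
      kind = "transmembrane", source = "truth", stringsAsFactors = FALSE)
    if (h < n_helices) {
      # loop outside the slab on the exit side of helix h
      exit_up <- up
      for (j in seq_len(loop_len)) {
        frac <- j / (loop_len + 1L)
        x <- helix_x(h) + frac * (helix_x(h + 1L) - helix_x(h))
        z <- if (exit_up) thickness + 4 + 2 * sin(pi * frac) else
          -4 - 2 * sin(pi * frac)
        add_residue(x, 4, z, loop_plddt)
      }
    }
  }
  # C-terminal tail on the exit side of the last helix
  last_up <- n_helices %% 2L == 1L
  for (j in seq_len(tail_len))
    add_residue(helix_x(n_helices) + j * 1.5, -3,
                if (last_up) thickness + 4 + j * 1.2 else -4 - j * 1.2,
                loop_plddt)
  atoms <- do.call(rbind, res)
  if (jitter_sd > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = jitter_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = jitter_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = jitter_sd)
  }
  model <- structure_model(protein_id, atoms)
  truth_df <- do.call(rbind, truth)
  truth_segments <- tms_segments(truth_df$start, truth_df$end,
                                 truth_df$entry, truth_df$exit,
                                 kind = "transmembrane", source = "truth")
  placement <- membrane_placement(model, geometry, truth_segments)
  list(model = model, geometry = geometry, truth = truth_segments,
       placement = placement)
}

#' Synthetic membrane hairpin fixture
#'
#' Generates a single re-entrant region: the chain enters the membrane from
#' below, penetrates to `depth` Angstrom and turns back out on the same side.
#' With `depth <= thickness - 10` the far boundary stays at least 10 Angstrom
#' away, so the planted segment classifies as re-entrant under the default
#' configuration.
#'
#' @param depth Maximum penetration into the slab (Angstrom, `0 < depth <
#'   thickness`).
#' @inheritParams make_helix_bundle
#' @return A list with `model`, `geometry`, `segment` (the planted
#'   membrane-embedded range) and `placement` (raw segments = the hairpin).
#' @export
make_hairpin <- function(depth = 12, thickness = 30, tail_len = 5L,
                         helix_plddt = 90, loop_plddt = 85, jitter_sd = 0,
                         seed = NULL, protein_id = "hairpin") {
  if (depth <= 0 || depth >= thickness)
    stop("depth must lie strictly between 0 and the membrane thickness")
  if (!is.null(seed)) set.seed(seed)
  rise <- 1.5
  leg <- as.integer(ceiling(depth / rise))
  geometry <- membrane_planar(c(0, 0, 1), c(0, thickness))
  res <- list()
  resno <- 0L
  add_residue <- function(x, y, z, plddt) {
    resno <<- resno + 1L
    res[[length(res) + 1L]] <<- data.frame(
      resno = resno, atom = c("N", "CA", "C", "O"),
      x = x + c(-0.6, 0, 0.6, 0.9), y = y + c(0.3, 0, -0.3, 0.5),
      z = z + c(-0.4, 0, 0.4, 0.6), plddt = plddt, stringsAsFactors = FALSE)
  }
  for (j in seq_len(tail_len))
    add_residue(-(tail_len - j + 1L) * 1.5, 3, -4 - (tail_len - j) * 1.2,
                loop_plddt)
  start <- resno + 1L
  for (k in seq_len(leg))  # descending leg of the hairpin goes up
    add_residue(0, 2.3 * sin(k), min((k - 0.5) * rise, depth - 0.25),
                helix_plddt)
  for (k in seq_len(leg))  # and back out on the same side
    add_residue(4, 2.3 * cos(k), min(depth - (k - 0.5) * rise, depth - 0.25),
                helix_plddt)
  seg_end <- resno
  for (j in seq_len(tail_len))
    add_residue(4 + j * 1.5, -3, -4 - j * 1.2, loop_plddt)
  atoms <- do.call(rbind, res)
  if (jitter_sd > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = jitter_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = jitter_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = jitter_sd)
  }
  model <- structure_model(protein_id, atoms)
  segs <- tms_segments(start, seg_end, entry = "side1", exit = "side1",
                       kind = "raw", source = "truth")
  list(model = model, geometry = geometry,
       segment = residue_range(start, seg_end),
       placement = membrane_placement(model, geometry, segs))
}

#' Wrap a planar fixture onto a large sphere
#'
#' Replaces the planar boundary geometry of a placement with two concentric
#' spheres of radius `radius` and `radius + d` whose surfaces coincide with
#' the two planes near the membrane axis (curvature error ~ x^2 / 2 radius,
#' negligible for `radius >> d` and fixture-scale coordinates). Exercises the
#' spherical distance branch without regenerating coordinates.
#'
#' @param placement A [membrane_placement()] with planar geometry.
#' @param radius Inner boundary radius (Angstrom), much larger than the
#'   membrane thickness.
#' @return The placement with spherical geometry.
#' @export
wrap_spherical <- function(placement, radius = 1e5) {
  stopifnot(inherits(placement, "membrane_placement"))
  g <- placement$geometry
  if (g$variant != "planar") stop("placement is not planar")
  center <- (g$offsets[[1L]] - radius) * g$normal
  placement$geometry <- membrane_spherical(
    center, c(radius, radius + diff(g$offsets)))
  placement
}

#' Block-structured PAE matrix fixture
#'
#' Builds an L x L pair-error matrix with `intra_value` inside the given
#' diagonal blocks (rigid domains), `inter_value` between blocks and zero on
#' the diagonal. A seeded fraction of off-diagonal entries is flipped across
#' the low-PAE line (intra becomes inter and vice versa, applied to both
#' directions of a pair) to emulate prediction noise.
#'
#' @param domain_lengths Integer vector of block lengths; `L = sum(...)`.
#' @param intra_value,inter_value Pair errors (Angstrom) inside and between
#'   blocks; `intra_value` should sit below and `inter_value` above the
#'   partitioning threshold.
#' @param flip_fraction Fraction in `[0, 1)` of residue pairs flipped.
#' @param seed Integer seed.
#' @return A [pae_matrix()].
#' @export
make_pae_blocks <- function(domain_lengths, intra_value = 4,
                            inter_value = 20, flip_fraction = 0,
                            seed = NULL) {
  domain_lengths <- as.integer(domain_lengths)
  if (any(domain_lengths < 1L)) stop("domain lengths must be >= 1")
  if (intra_value < 0 || inter_value < 0) stop("PAE values must be >= 0")
  if (flip_fraction < 0 || flip_fraction >= 1)
    stop("flip_fraction must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  L <- sum(domain_lengths)
  m <- matrix(inter_value, L, L)
  stop_at <- cumsum(domain_lengths)
  start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
  for (b in seq_along(domain_lengths)) {
    idx <- start_at[[b]]:stop_at[[b]]
    m[idx, idx] <- intra_value
  }
  diag(m) <- 0
  if (flip_fraction > 0) {
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    n_flip <- floor(flip_fraction * nrow(pairs))
    if (n_flip > 0L) {
      pick <- pairs[sample.int(nrow(pairs), n_flip), , drop = FALSE]
      cur <- m[pick]
      flipped <- ifelse(cur == intra_value, inter_value, intra_value)
      m[pick] <- flipped
      m[pick[, 2:1, drop = FALSE]] <- flipped
    }
  }
  pae_matrix(m)
}

#' Perturbed membrane placement fixture
#'
#' Derives a raw placement from a bundle's planted truth, emulating upstream
#' placement-tool failure modes: whole crossings can be dropped (misses) and
#' crossings can be split into two raw sub-segments separated by a gap
#' (broken/kinked helices), to exercise recovery and merging.
#'
#' @param bundle A fixture from [make_helix_bundle()] (or a list with
#'   `model`, `geometry`, `truth`).
#' @param drop_indices Integer indices (into the truth table) of crossings to
#'   withhold from the raw output.
#' @param split_spec List of `list(index =, gap =)` entries: the crossing at
#'   `index` is reported as two sub-segments separated by `gap` residues.
#' @param membrane_type Membrane type label carried on the placement.
#' @return A [membrane_placement()].
#' @export
make_placement <- function(bundle, drop_indices = integer(),
                           split_spec = list(), membrane_type = "") {
  truth <- as.data.frame(bundle$truth)
  n <- nrow(truth)
  drop_indices <- as.integer(drop_indices)
  if (any(drop_indices < 1L | drop_indices > n))
    stop("drop index out of range 1..", n)
  rows <- list()
  for (i in seq_len(n)) {
    if (i %in% drop_indices) next
    spl <- Filter(function(s) s$index == i, split_spec)
    if (length(spl)) {
      gap <- as.integer(spl[[1L]]$gap)
      len <- truth$end[[i]] - truth$start[[i]] + 1L
      left_len <- (len - gap) %/% 2L
      if (left_len < 1L || truth$start[[i]] + left_len + gap > truth$end[[i]])
        stop("split gap ", gap, " too large for crossing ", i)
      a <- truth[i, ]
      b <- truth[i, ]
      a$end <- truth$start[[i]] + left_len - 1L
      b$start <- a$end + gap + 1L
      rows[[length(rows) + 1L]] <- a
      rows[[length(rows) + 1L]] <- b
    } else {
      rows[[length(rows) + 1L]] <- truth[i, ]
    }
  }
  segs <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(tms_segments())
  segs$kind <- "raw"
  membrane_placement(bundle$model, bundle$geometry, restore_segments(segs),
                     membrane_type = membrane_type)
}

#' Perturbed multi-source annotation sets
#'
#' Copies a per-protein truth annotation into several sources and applies
#' per-(protein, source) perturbations, so the consistency category of every
#' protein is computable in closed form from the perturbation table:
#' `shift` moves all of a protein's ranges by `value` residues, `drop`
#' removes the first `value` ranges, and `add` appends a spurious 15-residue
#' range starting `value` residues past the protein's last truth range.
#'
#' @param truth Data frame with columns `protein`, `start`, `end`.
#' @param sources Character vector of source labels to emit.
#' @param perturbations `NULL`, or a data frame with columns `protein`,
#'   `source`, `action` (`"shift"`, `"drop"`, `"add"`) and `value`.
#' @return An [annotation_set()].
#' @export
make_annotation_sets <- function(truth, sources, perturbations = NULL) {
  stopifnot(all(c("protein", "start", "end") %in% names(truth)))
  rows <- list()
  for (src in sources) {
    for (pid in unique(truth$protein)) {
      sub <- truth[truth$protein == pid, c("start", "end"), drop = FALSE]
      pert <- if (!is.null(perturbations))
        perturbations[perturbations$protein == pid &
                        perturbations$source == src, , drop = FALSE] else
        perturbations
      if (!is.null(pert) && nrow(pert)) {
        for (k in seq_len(nrow(pert))) {
          act <- pert$action[[k]]
          val <- pert$value[[k]]
          if (act == "shift") {
            sub$start <- pmax(1L, sub$start + as.integer(val))
            sub$end <- sub$end + as.integer(val)
            sub$end <- pmax(sub$end, sub$start)
          } else if (act == "drop") {
            nd <- min(as.integer(val), nrow(sub))
            if (nd > 0L) sub <- sub[-seq_len(nd), , drop = FALSE]
          } else if (act == "add") {
            anchor <- max(truth$end[truth$protein == pid])
            s <- anchor + as.integer(val)
            sub <- rbind(sub, data.frame(start = s, end = s + 14L))
          } else {
            stop("unknown perturbation action: ", act)
          }
        }
      }
      if (nrow(sub))
        rows[[length(rows) + 1L]] <- data.frame(
          protein = pid, source = src, start = sub$start, end = sub$end,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(annotation_set())
  df <- do.call(rbind, rows)
  annotation_set(df$protein, df$source, df$start, df$end)
}
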