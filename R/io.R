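#' Read a predicted structure model
#'
#' Reads a single-chain coordinate file (PDB or mmCIF) whose temperature-
#' factor column carries the per-residue confidence (pLDDT), as in AlphaFold
#' model files. Only main-chain atoms (N, CA, C, O) are kept; residue
#' numbering is preserved exactly.
#'
#' @param path Coordinate file. `.cif`/`.mmcif` files are read as mmCIF,
#'   anything else as PDB.
#' @param confidence_scale `"auto"` (default), `"0-1"` or `"0-100"`. Scores on
#'   the 0-1 scale are multiplied by 100; `"auto"` treats the file as 0-1
#'   when the largest temperature factor is <= 1.
#' @param protein_id Identifier for the model; defaults to the file base name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, confidence_scale = c("auto", "0-1", "0-100"),
                           protein_id = NULL) {
  confidence_scale <- match.arg(confidence_scale)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else
    bio3d::read.pdb(path)
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atom)) stop("no ATOM records in ", path)
  chains <- unique(atom$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1L)
    stop("expected a single chain, found: ", paste(chains, collapse = ", "))
  if (all(is.na(atom$b)))
    stop("temperature-factor column is missing or empty in ", path)
  keep <- atom$elety %in% c("N", "CA", "C", "O")
  atom <- atom[keep, , drop = FALSE]
  if (anyDuplicated(paste(atom$resno, atom$elety)))
    stop("duplicate residue numbers (repeated atom names per residue) in ",
         path)
  b <- atom$b
  if (confidence_scale == "0-1" ||
      (confidence_scale == "auto" && max(b, na.rm = TRUE) <= 1))
    b <- b * 100
  # one confidence per residue: take it from the residue's first atom
  first <- !duplicated(atom$resno)
  plddt_map <- stats::setNames(b[first], atom$resno[first])
  atoms <- data.frame(resno = atom$resno, atom = atom$elety,
                      x = atom$x, y = atom$y, z = atom$z,
                      plddt = unname(plddt_map[as.character(atom$resno)]),
                      stringsAsFactors = FALSE)
  if (is.null(protein_id))
    protein_id <- tools::file_path_sans_ext(basename(path))
  structure_model(protein_id, atoms)
}

#' Write a structure model as a PDB file
#'
#' Pass-through writer used by the preprocessing subcommands; the confidence
#' score goes back into the temperature-factor column on the 0-100 scale.
#'
#' @param model A [structure_model()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (!nrow(a)) stop("cannot write an empty model")
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                   resid = rep("ALA", nrow(a)), elety = a$atom,
                   chain = rep("A", nrow(a)), b = a$plddt,
                   o = rep(1, nrow(a)))
  invisible(path)
}

# ---------------------------------------------------------------------------
# PAE JSON
# ---------------------------------------------------------------------------

#' Read a predicted-aligned-error matrix
#'
#' Accepts both AlphaFold PAE export schemas: the nested form
#' `{"predicted_aligned_error": [[...], ...]}` (optionally wrapped in a
#' one-element array, optionally under the key `pae`) and the legacy flat
#' triple form with `residue1`, `residue2` and `distance` arrays.
#'
#' @param path JSON file.
#' @return A [pae_matrix()].
#' @export
read_pae <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.data.frame(payload)) payload <- as.list(payload[1L, , drop = FALSE])
  if (is.list(payload) && is.null(names(payload)) && length(payload) >= 1L)
    payload <- payload[[1L]]
  m <- NULL
  for (key in c("predicted_aligned_error", "pae")) {
    if (!is.null(payload[[key]])) { m <- payload[[key]]; break }
  }
  if (!is.null(m)) {
    if (is.list(m)) {
      # a list (not matrix) from the parser means ragged rows
      if (length(unique(lengths(m))) != 1L) stop("ragged PAE rows in ", path)
      m <- do.call(rbind, m)
    }
    if (is.data.frame(m)) m <- as.matrix(m)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  } else if (!is.null(payload$residue1)) {
    r1 <- unlist(payload$residue1)
    r2 <- unlist(payload$residue2)
    d <- unlist(payload$distance)
    L <- max(r1, r2)
    if (length(r1) != L * L) stop("incomplete flat PAE payload in ", path)
    m <- matrix(NA_real_, L, L)
    m[cbind(r1, r2)] <- d
  } else {
    stop("unrecognized PAE schema in ", path)
  }
  if (any(is.na(m))) stop("missing PAE entries in ", path)
  if (nrow(m) != ncol(m)) stop("ragged PAE rows in ", path)
  pae_matrix(m)
}

#' @rdname read_pae
#' @param pae A [pae_matrix()].
#' @return For `write_pae()`: `path`, invisibly.
#' @export
write_pae <- function(pae, path) {
  stopifnot(inherits(pae, "pae_matrix"))
  m <- unclass(pae)
  payload <- list(list(predicted_aligned_error = m,
                       max_predicted_aligned_error = max(m)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Placement schema (AFTM-PLACEMENT/1)
# ---------------------------------------------------------------------------

#' Read and write membrane placements
#'
#' The native placement schema is a small line-oriented text format with the
#' versioned header `AFTM-PLACEMENT/1`: key-value lines (`protein`,
#' `membrane_type`, `geometry planar|spherical`, then `normal`/`offsets` or
#' `center`/`radii`, optionally `structure <path>` relative to the placement
#' file), followed by `segments <n>` and n whitespace-separated rows
#' `start end entry exit`. It abstracts the report of an upstream
#' membrane-positioning tool (boundary surfaces + embedded segments with
#' orientations) into a form that round-trips.
#'
#' @param path Placement file.
#' @param model Optional [structure_model()]; required when the file has no
#'   `structure` line, ignored otherwise.
#' @return A [membrane_placement()].
#' @export
read_placement <- function(path, model = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || lines[[1L]] != "AFTM-PLACEMENT/1")
    stop("not an AFTM-PLACEMENT/1 file: ", path)
  lines <- lines[-1L]
  fields <- list()
  seg_rows <- character()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(lines[[i]], "[[:space:]]+")[[1L]]
    key <- parts[[1L]]
    if (key == "segments") {
      n <- as.integer(parts[[2L]])
      if (is.na(n)) stop("bad segment count in ", path)
      if (i + n > length(lines)) stop("truncated segment table in ", path)
      seg_rows <- if (n > 0L) lines[(i + 1L):(i + n)] else character()
      i <- i + n + 1L
      next
    }
    fields[[key]] <- parts[-1L]
    i <- i + 1L
  }
  variant <- fields$geometry
  geometry <- switch(
    variant %||% "missing",
    planar = membrane_planar(as.numeric(fields$normal),
                             as.numeric(fields$offsets)),
    spherical = membrane_spherical(as.numeric(fields$center),
                                   as.numeric(fields$radii)),
    stop("unknown geometry variant in ", path, ": ",
         variant %||% "<missing>"))
  if (!is.null(fields$structure)) {
    spath <- file.path(dirname(path), paste(fields$structure, collapse = " "))
    model <- read_structure(spath, protein_id = fields$protein %||% NULL)
  }
  if (is.null(model))
    stop("placement file has no structure line; supply `model`")
  segs <- if (length(seg_rows)) {
    mat <- do.call(rbind, strsplit(seg_rows, "[[:space:]]+"))
    if (ncol(mat) != 4L) stop("segment rows need 4 fields in ", path)
    tms_segments(start = as.integer(mat[, 1L]), end = as.integer(mat[, 2L]),
                 entry = mat[, 3L], exit = mat[, 4L], kind = "raw")
  } else tms_segments()
  membrane_placement(model, geometry, segs,
                     membrane_type = paste(fields$membrane_type %||% "",
                                           collapse = " "))
}

#' @rdname read_placement
#' @param placement A [membrane_placement()].
#' @param structure_path Optional path (relative to the placement file) to
#'   write the model to and reference from the placement file; when `NULL`
#'   no structure line is emitted.
#' @return For `write_placement()`: `path`, invisibly.
#' @export
write_placement <- function(placement, path, structure_path = NULL) {
  stopifnot(inherits(placement, "membrane_placement"))
  g <- placement$geometry
  num <- function(v) paste(format(v, digits = 17, trim = TRUE), collapse = " ")
  out <- c("AFTM-PLACEMENT/1",
           paste("protein", placement$model$protein_id),
           if (nzchar(placement$membrane_type))
             paste("membrane_type", placement$membrane_type),
           paste("geometry", g$variant))
  out <- c(out, if (g$variant == "planar") {
    c(paste("normal", num(g$normal)), paste("offsets", num(g$offsets)))
  } else {
    c(paste("center", num(g$center)), paste("radii", num(g$radii)))
  })
  if (!is.null(structure_path)) {
    write_structure(placement$model,
                    file.path(dirname(path), structure_path))
    out <- c(out, paste("structure", structure_path))
  }
  s <- placement$raw_segments
  out <- c(out, paste("segments", nrow(s)),
           if (nrow(s)) paste(s$start, s$end, s$entry, s$exit))
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Alignment hits (BLAST/DIAMOND outfmt-6 dialect)
# ---------------------------------------------------------------------------

#' Read tabular alignment hits
#'
#' Parses the 12-column tab-separated BLAST/DIAMOND dialect (query, subject,
#' percent identity, alignment length, mismatches, gap openings, qstart,
#' qend, sstart, send, e-value, bit score). Two optional extra columns carry
#' the aligned query and subject sequences (with `-` gap characters) and
#' enable gap-aware coordinate projection.
#'
#' @param path Tab-separated hits file (no header). An empty file yields an
#'   empty table.
#' @return A data frame of class `alignment_hits` with columns `query`,
#'   `subject`, `identity`, `length`, `mismatches`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore` and (when present)
#'   `qseq`, `sseq`.
#' @export
read_hits <- function(path) {
  cols <- c("query", "subject", "identity", "length", "mismatches",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "",
                      quote = "", stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || !nrow(raw)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    class(df) <- c("alignment_hits", "data.frame")
    return(df)
  }
  if (ncol(raw) < 12L)
    stop("alignment hits need >= 12 tab-separated columns, found ", ncol(raw))
  df <- raw[, 1:12]
  names(df) <- cols
  if (ncol(raw) >= 14L) {
    df$qseq <- as.character(raw[[13L]])
    df$sseq <- as.character(raw[[14L]])
  }
  for (col in c("identity", "evalue", "bitscore"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("length", "mismatches", "gapopen", "qstart", "qend",
                "sstart", "send"))
    df[[col]] <- as.integer(df[[col]])
  if (any(df$qstart > df$qend) || any(df$sstart > df$send))
    stop("alignment hit with start > end")
  if (any(df$identity < 0 | df$identity > 100))
    stop("percent identity out of [0, 100]")
  class(df) <- c("alignment_hits", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# Annotation tables
# ---------------------------------------------------------------------------

#' Read and write annotation tables
#'
#' Annotation sets are stored as tab-separated tables with a header line and
#' columns `protein`, `source`, `start`, `end` (1-based inclusive). Rows are
#' written sorted by protein, source and start, so `read_annotations()` after
#' `write_annotations()` reproduces the input exactly.
#'
#' @param ann An [annotation_set()].
#' @param path TSV file path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns an [annotation_set()].
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty annotation file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("protein", "source", "start", "end")))
    stop("line 1: expected header 'protein\\tsource\\tstart\\tend'")
  body <- lines[-1L]
  body_ln <- which(nzchar(body)) + 1L
  body <- body[nzchar(body)]
  if (!length(body)) return(annotation_set())
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    ok <- length(p) == 4L && !is.na(suppressWarnings(as.integer(p[3L]))) &&
      !is.na(suppressWarnings(as.integer(p[4L]))) &&
      as.integer(p[3L]) >= 1L && as.integer(p[4L]) >= as.integer(p[3L])
    if (!ok)
      stop("line ", body_ln[[k]], ": malformed annotation row: ", body[[k]])
  }
  m <- do.call(rbind, parts)
  annotation_set(protein = m[, 1L], source = m[, 2L],
                 start = as.integer(m[, 3L]), end = as.integer(m[, 4L]))
}
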