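#' Run the full TMS annotation pipeline for one protein
#'
#' Orchestrates the whole procedure on already-parsed objects: trims the
#' model (annotated peptides, low-confidence residues), partitions the
#' protein into domains from its PAE matrix (reported, and used to group
#' per-domain placements), calls corrected TMSs on the full-model placement
#' and on every per-domain placement, and combines the tracks
#' ([combine_full_domain()]). Every correction (re-entrant exclusion, merge,
#' recovery) is recorded in a structured log, and each output segment carries
#' `provenance` (raw/merged/recovered) and `track` (full/domain) columns.
#'
#' @param model A [structure_model()] (the untrimmed full-length model).
#' @param pae Optional [pae_matrix()]; when `NULL`, partitioning is skipped
#'   (logged) and the run proceeds.
#' @param placement_full Optional full-model [membrane_placement()].
#' @param placements_domain List of per-domain [membrane_placement()]s.
#' @param peptide_ranges Optional peptide annotations (data frame with
#'   `start`/`end`, or list of [residue_range()]s) stripped before reporting.
#' @param cfg An [aftm_config()].
#' @param source Source label for the emitted annotation (default `"AFTM"`).
#' @return A list with `annotations` ([annotation_set()]), `tms` and
#'   `reentrant` ([tms_segments()] tables), `domains` (the
#'   [partition_domains()] table or `NULL`), `prepped_model` and `log`
#'   (character vector).
#' @export
run_aftm <- function(model, pae = NULL, placement_full = NULL,
                     placements_domain = list(), peptide_ranges = NULL,
                     cfg = aftm_config(), source = "AFTM") {
  stopifnot(inherits(model, "structure_model"))
  cfg <- as_config(cfg)
  log <- c(sprintf("protein %s", model$protein_id),
           sprintf("config: %s",
                   paste(names(cfg), unlist(cfg), sep = "=",
                         collapse = " ")))
  ids <- vapply(c(list(placement_full), placements_domain), function(p)
    if (is.null(p)) NA_character_ else p$model$protein_id, character(1L))
  ids <- ids[!is.na(ids)]
  if (length(ids) && !all(ids == model$protein_id))
    stop("protein id mismatch between model and placements: ",
         paste(unique(ids), collapse = ", "))
  prepped <- model
  if (!is.null(peptide_ranges)) {
    prepped <- strip_annotated_peptides(prepped, peptide_ranges)
    log <- c(log, sprintf("prep: stripped peptide ranges (%d residues left)",
                          length(residue_numbers(prepped))))
  }
  prepped <- trim_low_plddt(prepped, cfg)
  log <- c(log, sprintf("prep: trimmed residues with pLDDT < %g (%d left)",
                        cfg$plddt_min, length(residue_numbers(prepped))))
  domains <- NULL
  if (!is.null(pae)) {
    domains <- partition_domains(pae, cfg)
    log <- c(log, sprintf("partition: %d domain(s): %s", nrow(domains),
                          paste(domains$start, domains$end, sep = "-",
                                collapse = ", ")))
  } else {
    log <- c(log, "partition: no PAE matrix supplied, skipped")
  }
  track_call <- function(placement, track) {
    res <- call_tms(placement, cfg, source = source)
    n_raw <- nrow(placement$raw_segments)
    tm <- as.data.frame(res$tms)
    if (nrow(tm)) tm$track <- track
    log <<- c(log, sprintf(
      "call[%s]: %d raw -> %d TMS (%d re-entrant excluded, %d merged, %d recovered)",
      track, n_raw, nrow(tm), nrow(res$reentrant),
      sum(tm$provenance == "merged"), sum(tm$provenance == "recovered")))
    re <- as.data.frame(res$reentrant)
    if (nrow(re)) re$track <- track
    list(tms = tm, reentrant = re)
  }
  full_res <- if (!is.null(placement_full))
    track_call(placement_full, "full") else {
      log <- c(log, "call[full]: no full-model placement supplied")
      NULL
    }
  dom_res <- lapply(seq_along(placements_domain), function(i)
    track_call(placements_domain[[i]], paste0("domain", i)))
  empty_tm <- {
    e <- as.data.frame(tms_segments())
    e$provenance <- character(0)
    e$track <- character(0)
    e
  }
  full_tm <- if (is.null(full_res)) empty_tm else full_res$tms
  dom_tm <- lapply(dom_res, `[[`, "tms")
  dom_tm <- dom_tm[vapply(dom_tm, nrow, integer(1L)) > 0L]
  combined <- combine_full_domain(full_tm, dom_tm, cfg)
  log <- c(log, sprintf("combine: %d TMS after full/domain combination",
                        nrow(combined)))
  if (nrow(combined)) {
    for (i in seq_len(nrow(combined)))
      log <- c(log, sprintf("tms %d-%d %s->%s [%s, %s track]",
                            combined$start[[i]], combined$end[[i]],
                            combined$entry[[i]], combined$exit[[i]],
                            combined$provenance[[i]], combined$track[[i]]))
  }
  reent <- do.call(rbind, c(list(if (is.null(full_res)) NULL else
    full_res$reentrant), lapply(dom_res, `[[`, "reentrant")))
  if (is.null(reent)) reent <- as.data.frame(tms_segments())
  ann <- if (nrow(combined))
    annotation_set(rep(model$protein_id, nrow(combined)),
                   rep(source, nrow(combined)),
                   combined$start, combined$end) else annotation_set()
  list(annotations = ann, tms = restore_segments(combined),
       reentrant = restore_segments(reent), domains = domains,
       prepped_model = prepped, log = log)
}

#' Membrane type from a subcellular location label
#'
#' Maps free-text subcellular location annotations to the membrane type
#' labels understood by the upstream placement tool. Eight locations are
#' recognized (case-insensitively, by keyword): mitochondrial inner and outer
#' membranes, ER, Golgi, lysosome, endosome and vacuole membranes, and the
#' plasma membrane. Anything else maps to the undefined type (placement in
#' empty space).
#'
#' @param location Free-text location label (e.g. from a protein record).
#' @return Membrane type label; `"undefined"` when unrecognized.
#' @export
membrane_type_from_location <- function(location) {
  loc <- tolower(trimws(as.character(location %||% "")))
  if (!length(loc) || !nzchar(loc)) return("undefined")
  if (grepl("mitochond", loc) && grepl("inner", loc))
    return("mitochondrial inner membrane")
  if (grepl("mitochond", loc) && grepl("outer", loc))
    return("mitochondrial outer membrane")
  if (grepl("endoplasmic reticulum", loc) || grepl("\\ber\\b", loc))
    return("ER membrane (mammalian)")
  if (grepl("golgi", loc)) return("Golgi membrane")
  if (grepl("lysosom", loc)) return("lysosome membrane")
  if (grepl("endosom", loc)) return("endosome membrane")
  if (grepl("vacuol", loc)) return("vacuole membrane")
  if (grepl("plasma membrane", loc)) return("plasma membrane (mammalian)")
  "undefined"
}
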