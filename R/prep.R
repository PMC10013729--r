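#' Remove annotated peptide regions from a model
#'
#' Strips residues inside caller-supplied peptide annotations (signal
#' peptides, mitochondrial transit peptides) before membrane placement. The
#' surviving residues keep their original numbering.
#'
#' @param model A [structure_model()].
#' @param peptide_ranges List of [residue_range()]s (or a data frame with
#'   `start`/`end` columns); every range must lie within the model's
#'   numbering span.
#' @return The stripped `structure_model`.
#' @export
strip_annotated_peptides <- function(model, peptide_ranges) {
  stopifnot(inherits(model, "structure_model"))
  ranges <- normalize_range_list(peptide_ranges)
  if (!length(ranges)) return(model)
  rn <- residue_numbers(model)
  top <- if (length(rn)) max(rn) else 0L
  drop <- integer()
  for (r in ranges) {
    if (r[["end"]] > top)
      stop("peptide range [", r[["start"]], ", ", r[["end"]],
           "] outside model span (last residue ", top, ")")
    drop <- c(drop, r[["start"]]:r[["end"]])
  }
  model$atoms <- model$atoms[!model$atoms$resno %in% drop, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

normalize_range_list <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)),
                  function(i) residue_range(x$start[[i]], x$end[[i]])))
  }
  if (inherits(x, "residue_range")) return(list(x))
  lapply(x, as_residue_range)
}

#' Trim low-confidence residues
#'
#' Removes every residue with confidence below `cfg$plddt_min` (default 50 on
#' the 0-100 scale); disordered tails and linkers otherwise mislead the
#' membrane-placement optimization. The trimmed model may be fragmented: it
#' is kept as one model with numbering gaps.
#'
#' @param model A [structure_model()].
#' @param cfg An [aftm_config()].
#' @return The trimmed `structure_model` (possibly with zero residues).
#' @export
trim_low_plddt <- function(model, cfg = aftm_config()) {
  stopifnot(inherits(model, "structure_model"))
  cfg <- as_config(cfg)
  model$atoms <- model$atoms[model$atoms$plddt >= cfg$plddt_min, ,
                             drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' Extract a domain sub-model
#'
#' Returns the residues of `model` lying inside `domain`, with original
#' numbering, so segment coordinates called on the sub-model are directly
#' comparable to full-model coordinates.
#'
#' @param model A [structure_model()].
#' @param domain A [residue_range()].
#' @return A `structure_model` restricted to the domain.
#' @export
extract_domain <- function(model, domain) {
  stopifnot(inherits(model, "structure_model"))
  domain <- as_residue_range(domain)
  keep <- model$atoms$resno >= domain[["start"]] &
    model$atoms$resno <= domain[["end"]]
  if (!any(keep))
    stop("domain [", domain[["start"]], ", ", domain[["end"]],
         "] contains no residues of the model")
  model$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}
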