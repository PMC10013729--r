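#' Pipeline configuration
#'
#' All tunable thresholds of the annotation pipeline, with the defaults used
#' throughout. Comparison semantics follow the rules they implement: the
#' merge gap bound is exclusive (`gap < merge_gap_max`), the recovery gap
#' bound inclusive (`gap >= missing_gap_min`), and the identity filter strict
#' (`identity > identity_min`).
#'
#' @param pae_low_threshold Pair error (Angstrom) below which a residue pair
#'   counts as "low PAE" in domain partitioning. Default 12.
#' @param split_min_len Segments of at most this many residues are never
#'   split. Default 500.
#' @param split_big_len Length above which the lower ratio threshold
#'   (`ratio_big`) applies. Default 1000.
#' @param ratio_small Minimum intra/inter density ratio to split a segment of
#'   length in (`split_min_len`, `split_big_len`]. Default 20.
#' @param ratio_big Minimum ratio for segments longer than `split_big_len`.
#'   Default 10.
#' @param plddt_min Residues with confidence below this (0-100 scale) are
#'   trimmed before placement. Default 50.
#' @param tms_extension Residues added on each side of a raw segment before
#'   measuring boundary distances. Default 10.
#' @param boundary_dist_max Distance bound (Angstrom): a segment is
#'   transmembrane when its minimum distances to both boundaries are below
#'   this. Default 10.
#' @param merge_gap_max Same-orientation segments separated by fewer than
#'   this many residues are merged. Default 10.
#' @param missing_gap_min Same-orientation segments separated by at least
#'   this many residues trigger missing-TMS recovery. Default 15.
#' @param missing_halfwidth Residues taken on each side of the recovered
#'   center residue. Default 5.
#' @param match_overlap_min Minimum residue overlap for two TMS annotations
#'   to match (also the single-linkage clustering link). Default 10.
#' @param identity_min Percent-identity filter for alignment hits (strict
#'   `>`). Default 95.
#' @param min_fragment_len Smallest fragment a domain split may produce.
#'   Default 30.
#' @return A list of class `aftm_config`.
#' @export
aftm_config <- function(pae_low_threshold = 12,
                        split_min_len = 500L,
                        split_big_len = 1000L,
                        ratio_small = 20,
                        ratio_big = 10,
                        plddt_min = 50,
                        tms_extension = 10L,
                        boundary_dist_max = 10,
                        merge_gap_max = 10L,
                        missing_gap_min = 15L,
                        missing_halfwidth = 5L,
                        match_overlap_min = 10L,
                        identity_min = 95,
                        min_fragment_len = 30L) {
  cfg <- list(pae_low_threshold = as.numeric(pae_low_threshold),
              split_min_len = as.integer(split_min_len),
              split_big_len = as.integer(split_big_len),
              ratio_small = as.numeric(ratio_small),
              ratio_big = as.numeric(ratio_big),
              plddt_min = as.numeric(plddt_min),
              tms_extension = as.integer(tms_extension),
              boundary_dist_max = as.numeric(boundary_dist_max),
              merge_gap_max = as.integer(merge_gap_max),
              missing_gap_min = as.integer(missing_gap_min),
              missing_halfwidth = as.integer(missing_halfwidth),
              match_overlap_min = as.integer(match_overlap_min),
              identity_min = as.numeric(identity_min),
              min_fragment_len = as.integer(min_fragment_len))
  if (any(vapply(cfg, function(v) v <= 0, logical(1L))))
    stop("all configuration thresholds must be positive")
  if (cfg$ratio_small < cfg$ratio_big)
    stop("ratio_small must be >= ratio_big")
  structure(cfg, class = "aftm_config")
}

#' Read configuration overrides from a YAML file
#'
#' Unknown keys are an error; omitted keys keep their defaults.
#'
#' @param path YAML file whose top-level keys are [aftm_config()] arguments.
#' @param base Configuration the file overrides (default: package defaults).
#' @return An `aftm_config`.
#' @export
read_config <- function(path, base = aftm_config()) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(base)
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(unclass(base), vals)
  do.call(aftm_config, args)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(aftm_config())
  if (inherits(cfg, "aftm_config")) return(cfg)
  do.call(aftm_config, as.list(cfg))
}
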