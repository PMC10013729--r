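#' Fraction of low-error residue pairs
#'
#' The basic quantity of domain partitioning: among a set of residue pairs,
#' the fraction whose symmetrized pair error is below a threshold. The
#' possibly asymmetric PAE matrix is symmetrized with the elementwise minimum
#' of the two directions.
#'
#' @param pae A [pae_matrix()].
#' @param pairs Two-column matrix of residue index pairs (1-based).
#' @param threshold Pair-error cutoff in Angstrom (strict `<`).
#' @return Fraction in `[0, 1]`.
#' @export
low_pae_density <- function(pae, pairs, threshold) {
  stopifnot(inherits(pae, "pae_matrix"))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (!nrow(pairs)) stop("empty pair set")
  L <- pae_length(pae)
  if (any(pairs < 1L) || any(pairs > L)) stop("pair index out of 1..L")
  m <- unclass(pae)
  v <- pmin(m[pairs], m[pairs[, 2:1, drop = FALSE]])
  mean(v < threshold)
}

# Low-PAE indicator of the symmetrized matrix restricted to a segment.
low_indicator <- function(pae, segment, threshold) {
  idx <- segment[["start"]]:segment[["end"]]
  m <- unclass(pae)[idx, idx, drop = FALSE]
  (pmin(m, t(m)) < threshold) * 1
}

split_evaluation <- function(site, d_intra, d_inter) {
  ratio <- if (d_inter == 0) {
    if (d_intra > 0) Inf else 0
  } else d_intra / d_inter
  list(site = as.integer(site), d_intra = d_intra, d_inter = d_inter,
       ratio = ratio)
}

#' Evaluate one candidate split site
#'
#' Splitting a segment at `site` (the last residue of the left part) yields
#' two candidate sub-segments. The intra density `d_intra` is the fraction of
#' low-PAE pairs pooled over both sub-segments (all pairs i < j within
#' either); the inter density `d_inter` is the fraction of low-PAE pairs
#' among all left x right pairs. Their ratio measures how cleanly the site
#' separates two rigid bodies: `Inf` when `d_inter` is 0 with `d_intra > 0`,
#' and 0 for the degenerate 0/0 case (which never justifies a split).
#'
#' @param pae A [pae_matrix()].
#' @param segment [residue_range()] within `1..L`.
#' @param site Candidate split site; must leave at least
#'   `cfg$min_fragment_len` residues on each side.
#' @param cfg An [aftm_config()].
#' @return A list with `site`, `d_intra`, `d_inter`, `ratio`.
#' @export
evaluate_split <- function(pae, segment, site, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  segment <- as_residue_range(segment)
  site <- as.integer(site)
  lo <- segment[["start"]] + cfg$min_fragment_len - 1L
  hi <- segment[["end"]] - cfg$min_fragment_len
  if (site < lo || site > hi)
    stop("split site ", site, " outside admissible window [", lo, ", ", hi,
         "]")
  S <- low_indicator(pae, segment, cfg$pae_low_threshold)
  n <- nrow(S)
  k <- site - segment[["start"]] + 1L
  left <- 1:k
  right <- (k + 1L):n
  low_left <- (sum(S[left, left]) - sum(diag(S)[left])) / 2
  low_right <- (sum(S[right, right]) - sum(diag(S)[right])) / 2
  cross <- sum(S[left, right, drop = FALSE])
  intra_pairs <- k * (k - 1) / 2 + (n - k) * (n - k - 1) / 2
  split_evaluation(site, (low_left + low_right) / intra_pairs,
                   cross / (k * (n - k)))
}

#' Best split site of a segment
#'
#' Scans every admissible split site (leaving at least
#' `cfg$min_fragment_len` residues on each side) and returns the evaluation
#' with the maximal intra/inter density ratio; ties break to the smallest
#' site. The scan uses two-dimensional prefix sums of the low-PAE indicator,
#' so a whole segment is evaluated in O(L^2).
#'
#' @inheritParams evaluate_split
#' @return A split evaluation (as [evaluate_split()]) or `NULL` when no
#'   admissible site exists.
#' @export
best_split <- function(pae, segment, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  segment <- as_residue_range(segment)
  n <- range_length(segment)
  if (n < 2L * cfg$min_fragment_len) return(NULL)
  S <- low_indicator(pae, segment, cfg$pae_low_threshold)
  # P[i, j] = sum(S[1:i, 1:j])
  P <- apply(apply(S, 2L, cumsum), 1L, cumsum)
  P <- t(P)
  dsum <- cumsum(diag(S))
  ks <- cfg$min_fragment_len:(n - cfg$min_fragment_len)
  diagP <- P[cbind(ks, ks)]
  low_left <- (diagP - dsum[ks]) / 2
  cross <- P[ks, n] - diagP
  total_tri <- (P[n, n] - dsum[n]) / 2
  low_right <- total_tri - low_left - cross
  m <- n - ks
  intra_pairs <- ks * (ks - 1) / 2 + m * (m - 1) / 2
  d_intra <- (low_left + low_right) / intra_pairs
  d_inter <- cross / (ks * m)
  ratio <- ifelse(d_inter == 0, ifelse(d_intra > 0, Inf, 0),
                  d_intra / d_inter)
  best <- which.max(ratio)  # first maximum = smallest site
  split_evaluation(segment[["start"]] + ks[[best]] - 1L,
                   d_intra[[best]], d_inter[[best]])
}

split_ratio_threshold <- function(len, cfg) {
  if (len > cfg$split_big_len) cfg$ratio_big else cfg$ratio_small
}

#' Partition a protein into domains from its PAE matrix
#'
#' Recursively splits the protein: a segment is split at its best site (see
#' [best_split()]) when it is longer than `cfg$split_min_len` residues and
#' the intra/inter density ratio reaches the size-dependent threshold
#' (`ratio_big` for segments longer than `split_big_len` residues,
#' `ratio_small` otherwise). Recursion proceeds depth-first, left child
#' first, and stops when every segment is at most `split_min_len` residues
#' or admits no passing split.
#'
#' @inheritParams evaluate_split
#' @return A data frame of class `domain_segmentation` with columns `domain`
#'   (index), `start`, `end` and `ratio` (the ratio of the split that created
#'   the segment; `NA` for a never-split segment). Segments tile `1..L`
#'   contiguously.
#' @export
partition_domains <- function(pae, cfg = aftm_config()) {
  stopifnot(inherits(pae, "pae_matrix"))
  cfg <- as_config(cfg)
  L <- pae_length(pae)
  out <- list()
  recurse <- function(a, b, made_by) {
    len <- b - a + 1L
    if (len > cfg$split_min_len) {
      bs <- best_split(pae, residue_range(a, b), cfg)
      if (!is.null(bs) && bs$ratio >= split_ratio_threshold(len, cfg)) {
        recurse(a, bs$site, bs$ratio)
        recurse(bs$site + 1L, b, bs$ratio)
        return(invisible(NULL))
      }
    }
    out[[length(out) + 1L]] <<- data.frame(start = a, end = b,
                                           ratio = made_by)
    invisible(NULL)
  }
  recurse(1L, L, NA_real_)
  df <- do.call(rbind, out)
  df <- cbind(domain = seq_len(nrow(df)), df)
  class(df) <- c("domain_segmentation", "data.frame")
  df
}
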