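#' Match two TMS annotation lists
#'
#' Two TMSs match when they overlap by at least `cfg$match_overlap_min`
#' residues. Matching is a greedy one-to-one pairing by descending overlap
#' length (ties to the pair with the earlier start in `a`); two sources
#' annotate a protein consistently when every TMS in *both* lists is paired,
#' which implies equal TMS counts. Two empty lists are (vacuously)
#' consistent.
#'
#' @param a,b Data frames with `start`/`end` columns (sorted lists of TMS
#'   ranges for one protein from two sources).
#' @param cfg An [aftm_config()].
#' @return A list with `consistent` (flag) and `pairing` (data frame with
#'   columns `a`, `b`, `overlap`: indices into `a` and `b`).
#' @export
match_sets <- function(a, b, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  a <- as_range_df(a)
  b <- as_range_df(b)
  cand <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      ov <- min(a$end[[i]], b$end[[j]]) - max(a$start[[i]], b$start[[j]]) + 1L
      if (ov >= cfg$match_overlap_min)
        cand[[length(cand) + 1L]] <- c(i = i, j = j, ov = ov,
                                       astart = a$start[[i]])
    }
  }
  pairing <- data.frame(a = integer(), b = integer(), overlap = integer())
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, "ov"], cm[, "astart"], cm[, "i"], cm[, "j"]), ,
             drop = FALSE]
    used_a <- logical(nrow(a))
    used_b <- logical(nrow(b))
    for (k in seq_len(nrow(cm))) {
      i <- cm[k, "i"]; j <- cm[k, "j"]
      if (used_a[[i]] || used_b[[j]]) next
      used_a[[i]] <- TRUE
      used_b[[j]] <- TRUE
      pairing <- rbind(pairing, data.frame(a = i, b = j,
                                           overlap = cm[k, "ov"]))
    }
  }
  consistent <- nrow(pairing) == nrow(a) && nrow(pairing) == nrow(b)
  list(consistent = consistent, pairing = pairing)
}

#' Three-source consistency category of one protein
#'
#' Compares a protein's TMS lists from three sources A, U and H pairwise with
#' [match_sets()] and assigns one of five categories: `AUH` (all three
#' pairwise consistent), `AU\\H`, `AH\\U`, `HU\\A` (exactly that pair
#' consistent) or `A\\U\\H` (no pair consistent). In the non-transitive case
#' where exactly two pairs are consistent, the lexicographically first
#' consistent-pair label is assigned and a warning raised.
#'
#' @param annA,annU,annH Data frames with `start`/`end` columns: the
#'   protein's TMS lists from the three sources.
#' @param cfg An [aftm_config()].
#' @return One of `"AUH"`, `"AU\\H"`, `"AH\\U"`, `"HU\\A"`, `"A\\U\\H"`.
#' @export
categorize <- function(annA, annU, annH, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  au <- match_sets(annA, annU, cfg)$consistent
  ah <- match_sets(annA, annH, cfg)$consistent
  uh <- match_sets(annU, annH, cfg)$consistent
  n_ok <- sum(au, ah, uh)
  if (n_ok == 3L) return("AUH")
  if (n_ok == 0L) return("A\\U\\H")
  if (n_ok == 2L)
    warning("non-transitive pairwise consistency; assigning the first ",
            "consistent-pair label")
  c("AH\\U", "AU\\H", "HU\\A")[c(ah, au, uh)][1L]
}

#' Benchmark one protein against a single-pass reference
#'
#' Classifies a source's prediction for a protein whose reference annotation
#' (e.g. a curated single-pass TMP database) has exactly one TMS: `no_TM`
#' when the source predicts none, `multiple_TM` when it predicts two or more,
#' and `singleTM_match` / `singleTM_unmatch` when it predicts exactly one
#' that does / does not overlap the reference TMS by at least
#' `cfg$match_overlap_min` residues.
#'
#' @param pred Data frame with `start`/`end` columns: the source's TMS list.
#' @param reference_single The single reference TMS ([residue_range()]).
#' @param cfg An [aftm_config()].
#' @return One of `"no_TM"`, `"singleTM_match"`, `"singleTM_unmatch"`,
#'   `"multiple_TM"`.
#' @export
benchmark_single_pass <- function(pred, reference_single,
                                  cfg = aftm_config()) {
  cfg <- as_config(cfg)
  pred <- as_range_df(pred)
  ref <- as_residue_range(reference_single)
  if (nrow(pred) == 0L) return("no_TM")
  if (nrow(pred) >= 2L) return("multiple_TM")
  if (overlap_len(residue_range(pred$start[[1L]], pred$end[[1L]]), ref) >=
      cfg$match_overlap_min) "singleTM_match" else "singleTM_unmatch"
}

#' Count reference TMSs missed by a prediction
#'
#' Number of reference TMSs with no predicted TMS overlapping them by at
#' least `cfg$match_overlap_min` residues.
#'
#' @param reference,pred Data frames with `start`/`end` columns.
#' @param cfg An [aftm_config()].
#' @return Integer count of missed reference TMSs.
#' @export
count_missed <- function(reference, pred, cfg = aftm_config()) {
  cfg <- as_config(cfg)
  reference <- as_range_df(reference)
  pred <- as_range_df(pred)
  if (!nrow(reference)) return(0L)
  missed <- 0L
  for (i in seq_len(nrow(reference))) {
    ov <- if (nrow(pred)) vapply(seq_len(nrow(pred)), function(j)
      min(reference$end[[i]], pred$end[[j]]) -
        max(reference$start[[i]], pred$start[[j]]) + 1L, integer(1L)) else 0L
    if (!any(ov >= cfg$match_overlap_min)) missed <- missed + 1L
  }
  missed
}

#' Cross-tabulate per-protein TMS counts of two sources
#'
#' For every protein in the annotation set, counts its TMSs in `source_x` and
#' `source_y` (a source with no row for the protein contributes 0) and
#' tallies proteins per (count_x, count_y) cell — the data behind
#' TMS-count heatmaps comparing two annotation sources.
#'
#' @param ann An [annotation_set()].
#' @param source_x,source_y Source labels.
#' @return Data frame with columns `n_x`, `n_y`, `proteins`, sorted by
#'   (`n_x`, `n_y`); the `proteins` column sums to the number of distinct
#'   proteins in `ann`.
#' @export
crosstab_counts <- function(ann, source_x, source_y) {
  stopifnot(inherits(ann, "annotation_set"))
  prots <- unique(ann$protein)
  if (!length(prots))
    return(data.frame(n_x = integer(), n_y = integer(), proteins = integer()))
  nx <- vapply(prots, function(p)
    sum(ann$protein == p & ann$source == source_x), integer(1L))
  ny <- vapply(prots, function(p)
    sum(ann$protein == p & ann$source == source_y), integer(1L))
  tab <- as.data.frame(table(n_x = nx, n_y = ny), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(n_x = as.integer(tab$n_x), n_y = as.integer(tab$n_y),
                    proteins = as.integer(tab$Freq))
  out <- out[order(out$n_x, out$n_y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-protein comparison records over three sources
#'
#' Builds the per-protein comparison table behind the category summary: TMS
#' counts per source and the five-way consistency category.
#'
#' @param ann An [annotation_set()] containing the three sources.
#' @param sources Character vector of exactly three source labels, in (A, U,
#'   H) order.
#' @param cfg An [aftm_config()].
#' @return Data frame with one row per protein: `protein`, `n_A`, `n_U`,
#'   `n_H`, `category`.
#' @export
compare_sources <- function(ann, sources, cfg = aftm_config()) {
  stopifnot(inherits(ann, "annotation_set"), length(sources) == 3L)
  cfg <- as_config(cfg)
  prots <- unique(ann$protein)
  rows <- lapply(prots, function(p) {
    la <- annotation_ranges(ann, p, sources[[1L]])
    lu <- annotation_ranges(ann, p, sources[[2L]])
    lh <- annotation_ranges(ann, p, sources[[3L]])
    data.frame(protein = p, n_A = nrow(la), n_U = nrow(lu), n_H = nrow(lh),
               category = categorize(la, lu, lh, cfg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
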