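# Independent brute-force oracles and random-case generators used across the
# suite. These deliberately avoid the algorithmic shortcuts of the package
# implementations (prefix sums, union-find, single-pass merging).

# Per-site split evaluation by direct block sums over the symmetrized
# low-PAE indicator; argmax over all admissible sites, ties to the smallest.
oracle_best_split <- function(pae, segment, cfg = aftm_config()) {
  idx <- segment[["start"]]:segment[["end"]]
  m <- unclass(pae)[idx, idx, drop = FALSE]
  S <- pmin(m, t(m)) < cfg$pae_low_threshold
  n <- length(idx)
  if (n < 2L * cfg$min_fragment_len) return(NULL)
  ks <- cfg$min_fragment_len:(n - cfg$min_fragment_len)
  evals <- lapply(ks, function(k) {
    left <- 1:k
    right <- (k + 1L):n
    low_left <- sum(S[left, left][upper.tri(matrix(0, k, k))])
    low_right <- sum(S[right, right][upper.tri(matrix(0, n - k, n - k))])
    cross <- sum(S[left, right, drop = FALSE])
    d_intra <- (low_left + low_right) /
      (k * (k - 1) / 2 + (n - k) * (n - k - 1) / 2)
    d_inter <- cross / (k * (n - k))
    ratio <- if (d_inter == 0) {
      if (d_intra > 0) Inf else 0
    } else d_intra / d_inter
    list(site = segment[["start"]] + k - 1L, d_intra = d_intra,
         d_inter = d_inter, ratio = ratio)
  })
  evals[[which.max(vapply(evals, `[[`, numeric(1L), "ratio"))]]
}

# Fixpoint merging by repeated full rescan: find the first adjacent
# same-orientation pair with gap < merge_gap_max, merge it, start over.
oracle_merge <- function(segments, cfg = aftm_config()) {
  df <- as.data.frame(segments)
  repeat {
    done <- TRUE
    for (i in seq_len(max(0L, nrow(df) - 1L))) {
      same <- df$entry[[i]] == df$entry[[i + 1L]] &&
        df$exit[[i]] == df$exit[[i + 1L]]
      gap <- df$start[[i + 1L]] - df$end[[i]] - 1L
      if (same && gap < cfg$merge_gap_max) {
        df$end[[i]] <- df$end[[i + 1L]]
        df <- df[-(i + 1L), , drop = FALSE]
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  rownames(df) <- NULL
  df
}

# Transitive closure of the pairwise overlap >= threshold graph by repeated
# set expansion.
oracle_cluster <- function(df, cfg = aftm_config()) {
  n <- nrow(df)
  if (!n) return(list())
  ov <- function(i, j)
    min(df$end[[i]], df$end[[j]]) - max(df$start[[i]], df$start[[j]]) + 1L
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- i != j && ov(i, j) >= cfg$match_overlap_min
  clusters <- list()
  unassigned <- seq_len(n)
  while (length(unassigned)) {
    comp <- unassigned[[1L]]
    repeat {
      grown <- unique(c(comp, which(apply(
        adj[comp, , drop = FALSE], 2L, any))))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
    unassigned <- setdiff(unassigned, comp)
  }
  ord <- order(vapply(clusters, function(cl) min(df$start[cl]), integer(1L)))
  clusters[ord]
}

# Random sorted non-overlapping segment list with mixed orientations and a
# mix of small (< merge threshold) and large gaps.
random_segment_list <- function(n_max = 8L) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  if (n == 0L) return(tms_segments())
  start <- integer(n); end <- integer(n)
  pos <- sample.int(20L, 1L)
  for (i in seq_len(n)) {
    start[[i]] <- pos
    end[[i]] <- pos + sample.int(25L, 1L) + 4L
    pos <- end[[i]] + sample(c(sample.int(9L, 1L), 10L + sample.int(20L, 1L)),
                             1L)
  }
  orient <- sample(c("up", "down"), n, replace = TRUE)
  tms_segments(start, end,
               entry = ifelse(orient == "up", "side1", "side2"),
               exit = ifelse(orient == "up", "side2", "side1"),
               kind = "transmembrane", source = "sim")
}

# Uniform random rotation (QR of a Gaussian matrix, determinant fixed to +1)
# and a random translation.
random_rigid_transform <- function(scale = 50) {
  Q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  list(rotation = Q, translation = stats::rnorm(3L, sd = scale))
}

expect_same_ranges <- function(a, b) {
  expect_equal(data.frame(start = as.integer(a$start),
                          end = as.integer(a$end)),
               data.frame(start = as.integer(b$start),
                          end = as.integer(b$end)))
}
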