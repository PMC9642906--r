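# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the Ward oracle recomputes every candidate merge
# from scratch from the original distances via the centroid ESS identity, the
# auROC oracle enumerates all (positive, negative) pairs, and the Jaccard
# oracle enumerates bins.

# Ward.D2 agglomeration recomputed from scratch each step. For clusters A, B
# with original squared distances D2, the merge height satisfies
#   h^2 = 2 * |A||B|/(|A|+|B|) * ||c_A - c_B||^2,
#   ||c_A - c_B||^2 = S_AB/(|A||B|) - S_AA/(2|A|^2) - S_BB/(2|B|^2),
# where S_XY sums D2 over ordered member pairs. Ties broken like the
# implementation: lexicographically smallest (min member, max-of-mins) pair.
oracle_ward_d2 <- function(d) {
  d2 <- d^2
  clusters <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  merge_sets <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        A <- clusters[[i]]; B <- clusters[[j]]
        S_AB <- sum(d2[A, B, drop = FALSE])
        S_AA <- sum(d2[A, A, drop = FALSE])
        S_BB <- sum(d2[B, B, drop = FALSE])
        cd <- S_AB / (length(A) * length(B)) -
          S_AA / (2 * length(A)^2) - S_BB / (2 * length(B)^2)
        h2 <- 2 * length(A) * length(B) / (length(A) + length(B)) * cd
        key <- c(min(min(A), min(B)), max(min(A), min(B)))
        if (is.null(best) || h2 < best$h2 - 1e-12 ||
            (abs(h2 - best$h2) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, h2 = h2, key = key)
        }
      }
    }
    heights <- c(heights, sqrt(best$h2))
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    merge_sets[[length(merge_sets) + 1L]] <- merged
  }
  list(heights = heights, merge_sets = merge_sets)
}

# Member set created by each merge step of a ward_tree, for comparison with
# the oracle's merge trace.
tree_merge_sets <- function(tree) {
  members <- function(node) {
    if (node < 0L) return(-node)
    sort(c(members(tree$merge[node, 1L]), members(tree$merge[node, 2L])))
  }
  lapply(seq_along(tree$height), members)
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

oracle_jaccard <- function(x, y) {
  both <- !is.na(x) & !is.na(y)
  xs <- x[both]; ys <- y[both]
  u <- 0; disc <- 0
  for (i in seq_along(xs)) {
    if (xs[i] == 1 || ys[i] == 1) u <- u + 1
    if (xs[i] != ys[i]) disc <- disc + 1
  }
  if (u == 0) 1 else disc / u
}

# Random distance matrices with guaranteed real-valued Ward heights:
# Euclidean point clouds or Jaccard distances of random binary rows.
random_distance_matrix <- function(n, type = c("euclid", "jaccard")) {
  type <- match.arg(type)
  if (type == "euclid") {
    pts <- matrix(stats::rnorm(n * 3), n, 3)
    as.matrix(stats::dist(pts))
  } else {
    repeat {
      rows <- matrix(stats::rbinom(n * 10, 1, 0.4), n, 10)
      if (all(rowSums(rows) > 0)) break
    }
    m <- structure(rows, dimnames = list(paste0("t", seq_len(n)), NULL))
    pairwise_distance_matrix(m)
  }
}

# strip class/dimnames/attributes for plain-value matrix comparison
as_plain <- function(m) array(as.integer(m), dim(m))

make_traj <- function(rows, ids = paste0("P", seq_along(rows))) {
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  colnames(m) <- paste0("B", seq_len(ncol(m)))
  structure(m, grid = NULL, feature = "nsCAI",
            class = c("trajectory_matrix", class(m)))
}
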