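#' Jaccard distance between two binary trajectories
#'
#' The distance is the proportion of discordant bits among co-observed bins
#' where at least one trajectory is 1: bins missing in either trajectory are
#' excluded from numerator and denominator (pairwise-complete handling). If
#' the pair has co-observed bins but none with a 1, the pair is maximally
#' dissimilar for clustering purposes and the distance is 1. A pair with no
#' co-observed bin at all is incomparable and raises an error.
#'
#' @param x,y Vectors in \{0, 1, NA\} on the same grid.
#' @return Distance in \[0, 1\].
#' @examples
#' jaccard_distance(c(1, 0, 1), c(1, 1, 0))  # 2/3
#' @export
jaccard_distance <- function(x, y) {
  assert_that(length(x) == length(y), "trajectories must share the same grid")
  both <- !is.na(x) & !is.na(y)
  assert_that(any(both), "incomparable pair: no co-observed bins")
  xs <- x[both]; ys <- y[both]
  union <- sum(xs == 1 | ys == 1)
  if (union == 0) return(1)
  sum(xs != ys) / union
}

#' Pairwise Jaccard distance matrix
#'
#' Vectorised (cross-product based) computation of [jaccard_distance()] over
#' all row pairs of a trajectory matrix; results equal the scalar reference
#' exactly.
#'
#' @param m A `trajectory_matrix` (or any 0/1/NA matrix with rownames).
#' @return Symmetric numeric matrix with zero diagonal, entries in \[0, 1\],
#'   dimnames = participant ids.
#' @export
pairwise_distance_matrix <- function(m) {
  x <- unclass(m)
  storage.mode(x) <- "double"
  obs <- !is.na(x)
  xz <- x; xz[!obs] <- 0
  o <- matrix(as.double(obs), nrow(x))
  co_obs <- o %*% t(o)                       # co-observed bin counts
  if (nrow(x) > 1L) {
    bad <- which(co_obs == 0, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad) > 0L)
      stop(sprintf("incomparable pair(s) with no co-observed bins, e.g. %s / %s",
                   rownames(x)[bad[1, 1]], rownames(x)[bad[1, 2]]), call. = FALSE)
  }
  t11 <- xz %*% t(xz)                        # both 1 (necessarily co-observed)
  x1_yobs <- xz %*% t(o)                     # x==1 and y observed
  union <- x1_yobs + t(x1_yobs) - t11        # co-observed bins with >=1 one
  d <- (union - t11) / union                 # discordant / union
  d[union == 0] <- 1                         # no co-observed positive
  diag(d) <- 0
  d <- (d + t(d)) / 2                        # exact symmetry despite fp noise
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

validate_distance_matrix <- function(d) {
  assert_that(is.matrix(d) && nrow(d) == ncol(d), "distance matrix must be square")
  assert_that(!anyNA(d) && all(d >= 0), "distances must be non-negative and non-missing")
  assert_that(max(abs(d - t(d))) <= 1e-12, "distance matrix must be symmetric")
  assert_that(all(abs(diag(d)) <= 1e-12), "distance matrix must have a zero diagonal")
  invisible(d)
}

#' Ward agglomerative hierarchical clustering
#'
#' Agglomerates singletons into a bifurcating tree: at each step the pair of
#' clusters with the smallest Ward linkage is merged and linkage distances to
#' the remaining clusters are updated with the Lance-Williams recurrence. Two
#' Ward variants are supported: `"ward.D2"` (default; the recurrence operates
#' on squared distances and merge heights are their square roots) and
#' `"ward.D"` (the recurrence applied to the distances as given). Ties are
#' broken deterministically by the lexicographically smallest pair of
#' smallest-original-member indices, so results are platform independent.
#'
#' @param d Symmetric distance matrix (e.g. [pairwise_distance_matrix()]) or a
#'   `dist` object.
#' @param method `"ward.D2"` or `"ward.D"`.
#' @return An object of classes `ward_tree` and `hclust`: `merge` (n-1 x 2,
#'   negative entries are singletons), `height` (non-decreasing), `order`,
#'   `labels`, `method`. Works with [stats::cutree()] and plotting.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' ward_agglomerate(d)$height  # 1, sqrt(5)
#' @export
ward_agglomerate <- function(d, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (inherits(d, "dist")) d <- as.matrix(d)
  validate_distance_matrix(d)
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                          order = 1L, labels = labels, method = method,
                          call = match.call(), dist.method = "jaccard"),
                     class = c("ward_tree", "hclust")))
  }
  # working linkage matrix: squared for ward.D2 so the recurrence is linear
  w <- if (method == "ward.D2") d^2 else d
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  rep_id <- seq_len(n)                # smallest original member, for tie-breaks
  code <- -seq_len(n)                 # hclust node codes
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  big <- Inf
  wm <- w
  wm[!upper.tri(wm)] <- big

  for (step in seq_len(n - 1L)) {
    m <- min(wm)
    cand <- which(wm == m, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      # lexicographic tie-break on (min rep, max rep) of the pair
      lo <- pmin(rep_id[cand[, 1]], rep_id[cand[, 2]])
      hi <- pmax(rep_id[cand[, 1]], rep_id[cand[, 2]])
      cand <- cand[order(lo, hi)[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]          # i < j by upper.tri
    height[step] <- if (method == "ward.D2") sqrt(m) else m
    ci <- code[i]; cj <- code[j]
    # hclust row convention: singletons (negative) first ascending, then steps
    pair <- c(ci, cj)
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[step, ] <- pair

    ni <- size[i]; nj <- size[j]
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      wik <- ifelse(ks < i, wm[ks, i], wm[i, ks])
      wjk <- ifelse(ks < j, wm[ks, j], wm[j, ks])
      nk <- size[ks]
      wnew <- ((ni + nk) * wik + (nj + nk) * wjk - nk * m) / (ni + nj + nk)
      lo <- pmin(ks, i); hi <- pmax(ks, i)
      wm[cbind(lo, hi)] <- wnew
    }
    active[j] <- FALSE
    wm[j, ] <- big; wm[, j] <- big
    size[i] <- ni + nj
    rep_id[i] <- min(rep_id[i], rep_id[j])
    code[i] <- step
  }

  ord_rec <- function(node) {
    if (node < 0L) return(-node)
    c(ord_rec(merge[node, 1L]), ord_rec(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = ord_rec(n - 1L), labels = labels, method = method,
                 call = match.call(), dist.method = "jaccard"),
            class = c("ward_tree", "hclust"))
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("Ward agglomeration (%s) of %d trajectories; %d merges, max height %.4g\n",
              x$method, length(x$labels), length(x$height),
              if (length(x$height)) max(x$height) else 0))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges; connected components are the clusters. When a
#' trajectory matrix is supplied, labels 1..k are assigned in ascending order
#' of the clusters' mean trajectory positivity (cluster 1 = lowest-activity
#' group); otherwise clusters are numbered by first appearance.
#'
#' @param tree A [ward_agglomerate()] tree.
#' @param k Number of clusters, 1 <= k <= n.
#' @param m Optional `trajectory_matrix` whose rows match `tree$labels`.
#' @return Named integer vector of labels in 1..k over the clustered
#'   participants.
#' @export
cut_to_k <- function(tree, k, m = NULL) {
  n <- length(tree$labels)
  assert_that(k >= 1 && k <= n, sprintf("k must be in [1, %d]", n))
  raw <- if (n == 1L) stats::setNames(1L, tree$labels) else stats::cutree(tree, k = k)
  if (!is.null(m)) {
    mm <- unclass(m)[tree$labels, , drop = FALSE]
    act <- tapply(seq_along(raw), raw,
                  function(ix) mean(mm[ix, , drop = FALSE], na.rm = TRUE))
    ranks <- rank(unname(act), ties.method = "first")
    raw <- stats::setNames(as.integer(ranks[raw]), names(raw))
  }
  raw
}

#' Append the baseline cluster 0
#'
#' Participants who never report the behaviour during the observation window
#' (no positive bin; missing bins allowed) are excluded from hierarchical
#' clustering and appended as a reserved baseline cluster, label 0. The total
#' number of cluster labels is therefore k + 1.
#'
#' @param m A `trajectory_matrix` over **all** included participants.
#' @param labels Named labels 1..k from [cut_to_k()] over exactly the
#'   participants with at least one positive bin.
#' @return Object of class `cluster_assignment`: named integer vector over all
#'   rows of `m`, labels in \{0, 1, ..., k\}, with attribute `k`.
#' @export
assign_baseline_cluster <- function(m, labels) {
  never <- rownames(m)[rowSums(unclass(m) == 1L, na.rm = TRUE) == 0L]
  pos <- setdiff(rownames(m), never)
  assert_that(length(intersect(names(labels), never)) == 0L,
              "labels overlap the never-report (baseline) participants")
  assert_that(setequal(names(labels), pos),
              "labels must cover exactly the participants with >=1 positive bin")
  out <- stats::setNames(integer(nrow(m)), rownames(m))
  out[names(labels)] <- as.integer(labels)
  k <- if (length(labels)) max(as.integer(labels)) else 0L
  structure(out, k = k, class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- attr(x, "k")
  tab <- table(factor(unclass(x), levels = 0:k))
  cat(sprintf("Cluster assignment: %d participants, %d hierarchical cluster(s) + baseline cluster 0\n",
              length(x), k))
  print(tab)
  invisible(x)
}

#' Per-cluster behaviour trend curves
#'
#' For each cluster and semiannual bin, the proportion of participants
#' reporting the behaviour among those with a non-missing value, with the
#' denominators. The baseline cluster's curve is identically 0 by
#' construction (undefined where no member is observed).
#'
#' @param m A `trajectory_matrix`.
#' @param assignment A [assign_baseline_cluster()] result covering all rows.
#' @return Data frame: `cluster`, `bin`, `bin_label`, `prop` (NA when no
#'   member observed), `n_obs`.
#' @export
cluster_trend_curves <- function(m, assignment) {
  assert_that(setequal(names(assignment), rownames(m)),
              "assignment must cover all rows of the trajectory matrix")
  g <- attr(m, "grid")
  k <- attr(assignment, "k")
  x <- unclass(m)[names(assignment), , drop = FALSE]
  out <- do.call(rbind, lapply(0:k, function(cl) {
    rows <- x[unclass(assignment) == cl, , drop = FALSE]
    n_obs <- colSums(!is.na(rows))
    pos <- colSums(rows == 1L, na.rm = TRUE)
    data.frame(cluster = cl, bin = seq_len(ncol(x)),
               bin_label = g$labels %||% colnames(x),
               prop = ifelse(n_obs > 0, pos / n_obs, NA_real_),
               n_obs = n_obs, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a dendrogram
#'
#' @param tree A [ward_agglomerate()] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name dendrogram_export
NULL

#' @rdname dendrogram_export
#' @export
write_dendrogram_csv <- function(tree, path) {
  steps <- seq_along(tree$height)
  sizes <- vapply(steps, function(s) {
    cnt <- function(node) if (node < 0L) 1L else
      cnt(tree$merge[node, 1L]) + cnt(tree$merge[node, 2L])
    cnt(s)
  }, integer(1))
  utils::write.csv(data.frame(step = steps, left = tree$merge[, 1L],
                              right = tree$merge[, 2L], height = tree$height,
                              size = sizes),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname dendrogram_export
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (length(tree$labels) < 2L) {
    writeLines(sprintf("(%s);", tree$labels[1L] %||% "t1"), path)
    return(invisible(path))
  }
  ape::write.tree(ape::as.phylo(stats::as.hclust(tree)), file = path)
  invisible(path)
}
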