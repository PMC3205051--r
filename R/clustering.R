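#' Per-sample mean log2 ratio of a segment
#'
#' Phase 3 reduces an N x L segment to one object per sample -- the mean of
#' that sample's smoothed log2 ratios over the segment's probes -- so that
#' clustering partitions samples, never probes, and each sample lands in
#' exactly one cluster.
#'
#' @param x A smoothed `acgh_matrix`.
#' @param start_index,end_index Segment bounds as 1-based probe indices,
#'   inclusive (one row of [segment_matrix()]'s output).
#' @return Named numeric vector of N per-sample means.
#' @export
segment_means <- function(x, start_index, end_index) {
  stopifnot(inherits(x, "acgh_matrix"))
  m <- ncol(x$values)
  if (start_index < 1L || end_index > m || start_index > end_index)
    stop("segment bounds out of range", call. = FALSE)
  rowMeans(x$values[, start_index:end_index, drop = FALSE])
}

#' One-dimensional k-means (exact by default)
#'
#' Partitions scalars into `k` clusters minimising the within-cluster sum of
#' squares.  In one dimension the optimal clusters are contiguous runs of
#' the sorted values, so the global optimum is found exactly by dynamic
#' programming over split points (`method = "exact"`, the default); the
#' result is deterministic, permutation-equivariant, and needs no random
#' initialisation.  `method = "lloyd"` instead runs classical Lloyd
#' iteration seeded at the minimum, median, and maximum of the data
#' (matching the three-state gain/neutral/loss prior; evenly spaced
#' quantiles for k != 3), with ties going to the lower centroid and emptied
#' clusters re-seeded at the worst-fitted point.  Lloyd can stall in a
#' local optimum; it is kept for comparison with the classical algorithm.
#' When the data hold fewer than `k` distinct values, each distinct value
#' becomes its own cluster and `k` is effectively reduced
#' (`reduced = TRUE` in the result).
#'
#' @param values Numeric vector of N finite scalars.
#' @param k Number of clusters (default 3).
#' @param max_iter Iteration cap (Lloyd only).
#' @param tol Convergence tolerance on total centroid movement (Lloyd only).
#' @param method `"exact"` (dynamic program, global optimum) or `"lloyd"`.
#' @return List of class `kmeans1d`: `assignment` (cluster index per value,
#'   1..k_eff, clusters ordered by ascending centroid), `centroids`
#'   (ascending), `sizes`, `inertia` (within-cluster sum of squares),
#'   `iterations`, `reduced`.
#' @examples
#' kmeans_1d(c(-1, -1.1, 0, 0.05, 0.9, 1), k = 3)$centroids
#' @export
kmeans_1d <- function(values, k = 3L, max_iter = 100L, tol = 1e-8,
                      method = c("exact", "lloyd")) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer", call. = FALSE)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L || !all(is.finite(values)))
    stop("'values' must be a non-empty finite vector", call. = FALSE)
  distinct <- sort(unique(values))
  if (length(distinct) <= k) {
    assignment <- match(values, distinct)
    return(structure(list(
      assignment = assignment, centroids = distinct,
      sizes = tabulate(assignment, length(distinct)),
      inertia = 0, iterations = 0L,
      reduced = length(distinct) < k), class = "kmeans1d"))
  }
  if (method == "exact") return(kmeans_1d_exact(values, k))
  centroids <- if (k == 1L) mean(values)
    else if (k == 3L) c(min(values), stats::median(values), max(values))
    else stats::quantile(values, probs = seq(0, 1, length.out = k),
                         names = FALSE, type = 7)
  centroids <- sort(centroids)
  assignment <- assign_nearest(values, centroids)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    newc <- centroids
    for (j in seq_len(k)) {
      idx <- assignment == j
      if (any(idx)) {
        newc[j] <- mean(values[idx])
      } else {
        # re-seed an emptied cluster at the worst-fitted point
        far <- which.max(abs(values - centroids[assignment]))
        newc[j] <- values[far]
      }
    }
    ord <- order(newc)
    newc <- newc[ord]
    moved <- sum(abs(newc - centroids))
    centroids <- newc
    new_assignment <- assign_nearest(values, centroids)
    done <- identical(new_assignment, assignment) && moved <= tol
    assignment <- new_assignment
    if (done || iter >= max_iter) break
  }
  # final means so the fixed point is exact
  for (j in seq_len(k)) {
    idx <- assignment == j
    if (any(idx)) centroids[j] <- mean(values[idx])
  }
  ord <- order(centroids)
  centroids <- centroids[ord]
  assignment <- order(ord)[assignment]
  structure(list(
    assignment = assignment, centroids = centroids,
    sizes = tabulate(assignment, k),
    inertia = sum((values - centroids[assignment])^2),
    iterations = iter, reduced = FALSE), class = "kmeans1d")
}

# Exact 1-D k-means: optimal clusters are contiguous in sorted order, so
# minimise WSS by dynamic programming over the last-cluster start point.
# O(k n^2); segments rarely hold more than a few dozen samples.
kmeans_1d_exact <- function(values, k) {
  n <- length(values)
  ord <- order(values)
  v <- values[ord]
  cs <- c(0, cumsum(v))
  cs2 <- c(0, cumsum(v^2))
  wss <- function(i, j)  # within-SS of v[i..j]
    cs2[j + 1L] - cs2[i] - (cs[j + 1L] - cs[i])^2 / (j - i + 1L)
  cost <- matrix(Inf, k, n)      # cost[q, j]: best WSS of v[1..j] in q blocks
  split <- matrix(1L, k, n)      # start index of the last block
  for (j in seq_len(n)) cost[1L, j] <- wss(1L, j)
  if (k > 1L) for (q in 2:k) {
    for (j in q:n) {
      for (i in q:j) {
        cand <- cost[q - 1L, i - 1L] + wss(i, j)
        if (cand < cost[q, j]) {
          cost[q, j] <- cand
          split[q, j] <- i
        }
      }
    }
  }
  # backtrack block boundaries
  bounds <- integer(k + 1L)
  bounds[k + 1L] <- n
  j <- n
  for (q in k:1) {
    bounds[q] <- split[q, j] - 1L
    j <- bounds[q]
  }
  assignment_sorted <- rep(seq_len(k), times = diff(bounds))
  assignment <- integer(n)
  assignment[ord] <- assignment_sorted
  centroids <- vapply(seq_len(k), function(q)
    mean(v[(bounds[q] + 1L):bounds[q + 1L]]), numeric(1))
  structure(list(
    assignment = assignment, centroids = centroids,
    sizes = diff(bounds),
    inertia = cost[k, n], iterations = 0L,
    reduced = FALSE), class = "kmeans1d")
}

# nearest centroid, ties to the lower index
assign_nearest <- function(values, centroids) {
  d <- abs(outer(values, centroids, "-"))
  max.col(-d, ties.method = "first")
}

#' @export
print.kmeans1d <- function(x, ...) {
  cat(sprintf("1-D k-means: %d cluster(s)%s, inertia %.4g, %d iteration(s)\n",
              length(x$centroids), if (x$reduced) " (k reduced)" else "",
              x$inertia, x$iterations))
  cat("  centroids:", paste(signif(x$centroids, 4), collapse = ", "), "\n")
  invisible(x)
}
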