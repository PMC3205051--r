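#' Pearson correlation of two adjacent position vectors
#'
#' Cross-sample consistency measure of phase 2.  A position vector holds the
#' N smoothed log2 ratios at one probe; if the samples move synchronously
#' between two adjacent probes the correlation is near +/-1, while samples
#' that break ranks pull it towards 0.  A vector with zero variance (all
#' samples equal) makes the correlation undefined; it is returned as 0 so
#' that an adjacency where only some samples start moving is still seen as
#' inconsistent.
#'
#' @param v,w Numeric vectors of equal length N >= 2.
#' @return The product-moment correlation in \[-1, 1\]; 0 when either vector
#'   is constant.
#' @examples
#' pcc(c(0, 1, 0, 1, 0, 1), c(0, 10, 0, 10, 0, 10))  # 1
#' pcc(c(4, 5, 4, 5, 4, 5), c(5, 4, 5, 4, 5, 4))     # -1
#' @export
pcc <- function(v, w) {
  if (length(v) != length(w))
    stop("position vectors differ in length", call. = FALSE)
  if (length(v) < 2L)
    stop("correlation needs at least 2 samples", call. = FALSE)
  cv <- v - mean(v)
  cw <- w - mean(w)
  den <- sqrt(sum(cv^2) * sum(cw^2))
  if (den == 0) return(0)
  r <- sum(cv * cw) / den
  max(-1, min(1, r))
}

#' Manhattan distance between two position vectors
#'
#' Sum over samples of the absolute log2-ratio difference.  Catches
#' synchronized jumps that leave the correlation at +/-1 but move the whole
#' panel, the complement of [pcc()] in the breakpoint rule.
#'
#' @param v,w Numeric vectors of equal length N >= 1.
#' @return Non-negative sum of absolute differences.
#' @examples
#' manhattan_dist(c(0, 1, 0, 1, 0, 1), c(0, 10, 0, 10, 0, 10))  # 27
#' @export
manhattan_dist <- function(v, w) {
  if (length(v) != length(w))
    stop("position vectors differ in length", call. = FALSE)
  sum(abs(v - w))
}

#' Breakpoint determination rule for one adjacency
#'
#' Position i+1 becomes a breakpoint when the adjacent position vectors stop
#' being consistent: either their absolute correlation falls below
#' `theta_pcc`, or the mean per-sample absolute jump (Manhattan distance
#' divided by N) exceeds `theta_dist`.  High correlation is necessary but
#' not sufficient -- a panel-wide jump keeps correlation at 1 -- hence the
#' OR with the distance test.  When both vectors are constant the
#' correlation carries no information and the distance test alone decides,
#' so a flat stretch of identical probes is never broken.
#'
#' @param v,w Adjacent position vectors (length N >= 2).
#' @param theta_pcc,theta_dist Thresholds, see [mgvd_config()].
#' @return `TRUE` if the position of `w` starts a new segment.
#' @examples
#' is_breakpoint(c(0, 1, 0, 1, 0, 1), c(0, 10, 0, 10, 0, 10), 0.8, 0.075)
#' is_breakpoint(c(4, 5, 4, 5, 4, 5), c(5, 4, 5, 4, 5, 4), 0.8, 1.5)
#' @export
is_breakpoint <- function(v, w, theta_pcc, theta_dist) {
  if (length(v) != length(w))
    stop("position vectors differ in length", call. = FALSE)
  if (length(v) < 2L)
    stop("breakpoint test needs at least 2 samples", call. = FALSE)
  md <- manhattan_dist(v, w) / length(v)
  if (md > theta_dist) return(TRUE)
  both_flat <- stats::var(v) == 0 && stats::var(w) == 0
  !both_flat && abs(pcc(v, w)) < theta_pcc
}

#' Joint segmentation of a multi-sample matrix
#'
#' Applies the breakpoint rule to every adjacent pair of position vectors
#' and cuts the probe index range into contiguous segments.  Segments tile
#' the whole matrix: every probe belongs to exactly one segment, in order.
#'
#' @param x A smoothed `acgh_matrix` with N >= 2 samples.
#' @param cfg An [mgvd_config()] supplying `theta_pcc` and `theta_dist`.
#' @return A data.frame with one row per segment: `start_index`, `end_index`
#'   (1-based probe indices, inclusive), `start_bp`, `end_bp` (half-open
#'   genomic span), `n_probes`.
#' @export
segment_matrix <- function(x, cfg = mgvd_config()) {
  stopifnot(inherits(x, "acgh_matrix"))
  if (!x$smoothed)
    stop("segmentation expects a smoothed matrix (run smooth_probes first)",
         call. = FALSE)
  n <- nrow(x$values); m <- ncol(x$values)
  if (n < 2L)
    stop("cross-sample segmentation needs at least 2 samples", call. = FALSE)
  brk <- if (m > 1L) which(adjacent_breaks(x$values, cfg$theta_pcc,
                                           cfg$theta_dist)) + 1L
         else integer(0)
  starts <- c(1L, brk)
  ends <- c(brk - 1L, m)
  data.frame(start_index = starts, end_index = ends,
             start_bp = x$start[starts], end_bp = x$end[ends],
             n_probes = ends - starts + 1L)
}

# Vectorized breakpoint rule over all M-1 adjacencies; same arithmetic as
# pcc()/manhattan_dist()/is_breakpoint() applied column-wise.
adjacent_breaks <- function(vals, theta_pcc, theta_dist) {
  n <- nrow(vals); m <- ncol(vals)
  a <- vals[, -m, drop = FALSE]
  b <- vals[, -1L, drop = FALSE]
  md <- colSums(abs(b - a)) / n
  ca <- sweep(a, 2L, colMeans(a))
  cb <- sweep(b, 2L, colMeans(b))
  ssa <- colSums(ca^2)
  ssb <- colSums(cb^2)
  den <- sqrt(ssa * ssb)
  r <- ifelse(den > 0, colSums(ca * cb) / den, 0)
  r <- pmax(-1, pmin(1, r))
  both_flat <- ssa == 0 & ssb == 0
  md > theta_dist | (!both_flat & abs(r) < theta_pcc)
}
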