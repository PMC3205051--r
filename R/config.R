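#' Tuning parameters for CNVZ detection
#'
#' Bundles every tunable of the four-phase detector into one validated list.
#' The defaults are the operating point recommended for ~50 bp-resolution
#' oligo aCGH panels: an 11-probe moving average (roughly the minimum
#' expected CNV size of ~550 bp), a correlation threshold of 0.8 for
#' cross-sample consistency, and score gates of 0.5 (candidate) and 3.5
#' (outlier trim).
#'
#' @param window Moving-average window in probes; odd, >= 1.
#' @param theta_pcc Breakpoint threshold on the absolute Pearson correlation
#'   of adjacent position vectors, in \[0, 1\].  Adjacent positions whose
#'   correlation falls below it are declared inconsistent.
#' @param theta_dist Breakpoint threshold on the Manhattan distance between
#'   adjacent position vectors divided by the sample count, i.e. the mean
#'   per-sample absolute log2-ratio jump.  Must be positive.
#' @param theta_cnvz Lower gate on the cluster-geometry score f: segments
#'   with `theta_cnvz < f < theta_outlier` become candidate zones.
#' @param theta_outlier Upper gate on f; segments at or above it are trimmed
#'   as neutral outliers attributed to a complete loss in the reference
#'   sample.  Must exceed `theta_cnvz`.
#' @param merge_gap_bp Candidate zones closer than this gap (bp, strict `<`)
#'   are merged.
#' @param min_cnvz_bp Zones shorter than this span (bp, strict `<`) are
#'   discarded after merging; ~0.5 Kbp is the platform's minimum CNV size.
#' @param k Number of clusters per segment; fixed at 3 for the
#'   gain/neutral/loss model.
#' @param kmeans_max_iter,kmeans_tol Iteration cap and centroid-movement
#'   convergence tolerance of the 1-D k-means.
#' @param seed Integer seed recorded with results (the detector itself is
#'   deterministic; the seed matters only for simulation helpers).
#'
#' @return An object of class `mgvd_config`.
#' @examples
#' cfg <- mgvd_config(theta_dist = 0.05)
#' cfg$theta_dist
#' @export
mgvd_config <- function(window = 11L,
                        theta_pcc = 0.8,
                        theta_dist = 0.075,
                        theta_cnvz = 0.5,
                        theta_outlier = 3.5,
                        merge_gap_bp = 1000L,
                        min_cnvz_bp = 500L,
                        k = 3L,
                        kmeans_max_iter = 100L,
                        kmeans_tol = 1e-8,
                        seed = 1L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 1", call. = FALSE)
  if (!is.numeric(theta_pcc) || theta_pcc < 0 || theta_pcc > 1)
    stop("'theta_pcc' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(theta_dist) || theta_dist <= 0)
    stop("'theta_dist' must be positive", call. = FALSE)
  if (!is.numeric(theta_cnvz) || !is.numeric(theta_outlier) ||
      theta_cnvz <= 0 || theta_cnvz >= theta_outlier)
    stop("need 0 < theta_cnvz < theta_outlier", call. = FALSE)
  if (merge_gap_bp < 0 || min_cnvz_bp < 0)
    stop("'merge_gap_bp' and 'min_cnvz_bp' must be non-negative", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer", call. = FALSE)
  structure(
    list(window = window, theta_pcc = theta_pcc, theta_dist = theta_dist,
         theta_cnvz = theta_cnvz, theta_outlier = theta_outlier,
         merge_gap_bp = as.numeric(merge_gap_bp),
         min_cnvz_bp = as.numeric(min_cnvz_bp),
         k = k, kmeans_max_iter = as.integer(kmeans_max_iter),
         kmeans_tol = kmeans_tol, seed = as.integer(seed)),
    class = "mgvd_config")
}

#' @export
print.mgvd_config <- function(x, ...) {
  cat("CNVZ detection parameters:\n")
  cat(sprintf("  window        : %d probes\n", x$window))
  cat(sprintf("  theta_pcc     : %g\n", x$theta_pcc))
  cat(sprintf("  theta_dist    : %g (mean per-sample jump)\n", x$theta_dist))
  cat(sprintf("  theta_cnvz    : %g\n", x$theta_cnvz))
  cat(sprintf("  theta_outlier : %g\n", x$theta_outlier))
  cat(sprintf("  merge gap     : %g bp, min zone: %g bp, k = %d\n",
              x$merge_gap_bp, x$min_cnvz_bp, x$k))
  invisible(x)
}
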