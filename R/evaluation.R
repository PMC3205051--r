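#' Base-pair confusion counts of calls against a truth set
#'
#' Every base pair of the evaluated span is classified: TP if covered by
#' both a call and a truth interval, FP if called only, FN if truth only,
#' TN otherwise.  Counting base pairs rather than events gives partial
#' credit for partial overlap and makes FDR/sensitivity exact.  All
#' intervals are half-open `[start, end)`; overlapping records within calls
#' or truth are coalesced before counting so nothing is double-counted.
#'
#' @param calls,truth data.frames with numeric `start` and `end` columns
#'   (extra columns ignored), or two-column matrices; zero-row inputs are
#'   allowed.
#' @param span Length-2 numeric `c(start, end)` of the evaluated region;
#'   every interval must lie inside it.
#' @return List with integer-valued `tp`, `fp`, `fn`, `tn` summing to
#'   `span[2] - span[1]`.
#' @examples
#' basepair_confusion(data.frame(start = 0, end = 150),
#'                    data.frame(start = 100, end = 300), c(0, 1000))
#' @export
basepair_confusion <- function(calls, truth, span) {
  if (length(span) != 2L || span[2] <= span[1])
    stop("'span' must be c(start, end) with start < end", call. = FALSE)
  a <- coalesce_intervals(calls)
  b <- coalesce_intervals(truth)
  for (iv in list(a, b))
    if (nrow(iv) && (min(iv$start) < span[1] || max(iv$end) > span[2]))
      stop("interval outside the evaluated span", call. = FALSE)
  tp <- interval_overlap(a, b)
  called <- sum(a$end - a$start)
  truthbp <- sum(b$end - b$start)
  fp <- called - tp
  fn <- truthbp - tp
  list(tp = tp, fp = fp, fn = fn,
       tn = (span[2] - span[1]) - tp - fp - fn)
}

# sort + union of half-open intervals; returns data.frame(start, end)
coalesce_intervals <- function(x) {
  x <- as.data.frame(x)
  if (nrow(x) == 0L) return(data.frame(start = numeric(), end = numeric()))
  if (is.null(x$start)) { colnames(x)[1:2] <- c("start", "end") }
  if (any(x$end <= x$start)) stop("empty or inverted interval", call. = FALSE)
  x <- x[order(x$start), c("start", "end"), drop = FALSE]
  grp <- cumsum(c(1, as.integer(x$start[-1L] > cummax(x$end[-nrow(x)]))))
  data.frame(start = as.numeric(tapply(x$start, grp, min)),
             end = as.numeric(tapply(x$end, grp, max)))
}

# total overlap (bp) between two coalesced interval sets
interval_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$end[j] <= a$start[i]) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b$start[k] < a$end[i]) {
      tot <- tot + max(0, min(a$end[i], b$end[k]) - max(a$start[i], b$start[k]))
      k <- k + 1L
    }
  }
  tot
}

#' FDR, sensitivity and F1 from base-pair confusion counts
#'
#' `fdr = FP / (FP + TP)` (0, flagged, when nothing was called),
#' `sensitivity = TP / (TP + FN)`, and F1 as the harmonic mean of precision
#' (`1 - fdr`) and sensitivity, 0 when both are degenerate.  An empty truth
#' set leaves sensitivity undefined and is an error.
#'
#' @param counts Output of [basepair_confusion()].
#' @return List with `fdr`, `sensitivity`, `f1`, and `no_calls` flag.
#' @examples
#' cm <- basepair_confusion(data.frame(start = 0, end = 150),
#'                          data.frame(start = 100, end = 300), c(0, 1000))
#' cnv_metrics(cm)
#' @export
cnv_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn, counts$tn) < 0))
    stop("negative confusion count", call. = FALSE)
  if (tp + fn == 0)
    stop("empty truth set: sensitivity is undefined", call. = FALSE)
  no_calls <- tp + fp == 0
  fdr <- if (no_calls) 0 else fp / (fp + tp)
  sens <- tp / (tp + fn)
  prec <- 1 - fdr
  f1 <- if (no_calls || prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  list(fdr = fdr, sensitivity = sens, f1 = f1, no_calls = no_calls)
}

#' Two-parameter sweep of the detector against a truth set
#'
#' Re-runs detection over a grid of `theta_dist` x `theta_cnvz` values and
#' scores each run at base-pair resolution.  Smoothing, segmentation,
#' clustering and scoring depend only on `theta_dist`, so they are computed
#' once per `theta_dist` and reused across the `theta_cnvz` grid; cached and
#' uncached runs are bit-identical.  The default grids reproduce the
#' 9 x 10 = 90-experiment design used to tune the detector per chromosome:
#' `theta_dist` from 0.025 in steps of 0.025, and ten `theta_cnvz` values
#' from 0.05 to 1.4 in steps of 0.15.
#'
#' @param x A raw `acgh_matrix`.
#' @param truth data.frame of truth intervals (`start`, `end` in bp).
#' @param dist_grid,cnvz_grid Non-empty numeric grids.
#' @param cfg Base [mgvd_config()]; its `theta_dist`/`theta_cnvz` are
#'   overridden by the grids.
#' @param span Evaluated region, default the probed span of `x`.
#' @return data.frame of class `mgvd_sweep` with one row per grid point:
#'   `theta_dist`, `theta_cnvz`, `tp`, `fp`, `fn`, `tn`, `fdr`,
#'   `sensitivity`, `f1`, `called_bp`, `n_cnvz`; the argmax-F1 row index is
#'   attached as attribute `best`.
#' @export
parameter_sweep <- function(x, truth,
                            dist_grid = seq(0.025, by = 0.025, length.out = 9),
                            cnvz_grid = seq(0.05, by = 0.15, length.out = 10),
                            cfg = mgvd_config(), span = NULL) {
  stopifnot(inherits(x, "acgh_matrix"))
  if (length(dist_grid) == 0L || length(cnvz_grid) == 0L)
    stop("parameter grids must be non-empty", call. = FALSE)
  if (x$smoothed) sm <- x else sm <- smooth_probes(x, cfg$window)
  if (is.null(span)) span <- c(min(x$start), max(x$end))
  truth <- coalesce_intervals(truth)
  clipped <- truth
  clipped$start <- pmax(clipped$start, span[1])
  clipped$end <- pmin(clipped$end, span[2])
  if (!isTRUE(all.equal(clipped, truth)))
    warning("truth intervals clipped to the evaluated span")
  truth <- clipped[clipped$end > clipped$start, , drop = FALSE]
  rows <- vector("list", length(dist_grid) * length(cnvz_grid))
  r <- 0L
  for (td in dist_grid) {
    cfg_d <- cfg
    cfg_d$theta_dist <- td
    scored <- mgvd_score(sm, cfg_d)
    for (tc in cnvz_grid) {
      cfg_c <- cfg_d
      cfg_c$theta_cnvz <- tc
      calls <- mgvd_call(scored, sm, cfg_c)
      cm <- basepair_confusion(calls$cnvz, truth, span)
      met <- cnv_metrics(cm)
      r <- r + 1L
      rows[[r]] <- data.frame(
        theta_dist = td, theta_cnvz = tc,
        tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
        fdr = met$fdr, sensitivity = met$sensitivity, f1 = met$f1,
        called_bp = cm$tp + cm$fp, n_cnvz = nrow(calls$cnvz))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.max(out$f1)
  class(out) <- c("mgvd_sweep", "data.frame")
  out
}

#' @export
print.mgvd_sweep <- function(x, ...) {
  cat(sprintf("parameter sweep: %d runs\n", nrow(x)))
  b <- attr(x, "best")
  cat(sprintf("best F1 = %.3f at theta_dist = %g, theta_cnvz = %g (sens %.3f, FDR %.3f)\n",
              x$f1[b], x$theta_dist[b], x$theta_cnvz[b],
              x$sensitivity[b], x$fdr[b]))
  NextMethod()
}
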