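#' @export
print.mgvd <- function(x, ...) {
  r <- x$report
  cat(sprintf("Common-CNV zone detection on %s (%d samples x %d probes)\n",
              x$chrom, r["n_samples"], r["n_probes"]))
  cat(sprintf("  segments: %d, candidates: %d, outlier segments: %d\n",
              r["n_segments"], r["n_candidates"], r["n_outlier_segments"]))
  cat(sprintf("  CNVZs: %d, per-sample CNVs: %d\n",
              r["n_cnvz"], r["n_sample_cnvs"]))
  invisible(x)
}

#' Summary of a CNV-zone detection
#'
#' @param object An `mgvd` fit.
#' @param ... Unused.
#' @return `object`, invisibly, after printing zone and per-sample tables.
#' @export
summary.mgvd <- function(object, ...) {
  print(object)
  cat(sprintf("  flag threshold mu + sigma = %.4g (over %d centroids)\n",
              object$centroid_stats$mu + object$centroid_stats$sigma,
              object$centroid_stats$n))
  if (nrow(object$cnvz)) {
    cat("\nCalled zones:\n")
    z <- object$cnvz
    z$samples <- ifelse(nchar(z$samples) > 40,
                        paste0(substr(z$samples, 1, 37), "..."), z$samples)
    print(z, row.names = FALSE)
  } else cat("\nNo zones called.\n")
  if (nrow(object$reference_report)) {
    cat("\nSegments suppressed as case-1 reference-loss outliers:\n")
    print(object$reference_report, row.names = FALSE)
  }
  invisible(object)
}

#' Plot a CNV-zone detection
#'
#' Draws every sample's log2-ratio track (smoothed by default) against
#' genomic position, shades called zones, and marks case-1 suppressed
#' segments.
#'
#' @param x An `mgvd` fit.
#' @param smoothed Plot the smoothed (`TRUE`, default) or raw tracks.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.mgvd <- function(x, smoothed = TRUE, ...) {
  m <- if (smoothed) x$smoothed else x$raw
  pos <- (m$start + m$end) / 2
  graphics::matplot(pos, t(m$values), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.5),
                    xlab = sprintf("position on %s (bp)", x$chrom),
                    ylab = if (smoothed) "smoothed log2 ratio"
                           else "log2 ratio", ...)
  if (nrow(x$cnvz))
    graphics::rect(x$cnvz$start, graphics::par("usr")[3],
                   x$cnvz$end, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("firebrick", 0.15),
                   border = NA)
  if (nrow(x$reference_report))
    graphics::rect(x$reference_report$start, graphics::par("usr")[3],
                   x$reference_report$end, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Export called zones as BED6+
#'
#' Columns: chrom, start, end, name, score (f), strand ("."), then rho,
#' n_samples, the signed sample list, and the reference annotation.
#'
#' @param fit An `mgvd` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnvz_bed <- function(fit, path) {
  stopifnot(inherits(fit, "mgvd"))
  z <- fit$cnvz
  bed <- data.frame(chrom = z$chrom, start = format_bp(z$start),
                    end = format_bp(z$end), name = z$name,
                    score = z$score, strand = ".",
                    rho = z$rho, n_samples = z$n_samples,
                    samples = z$samples,
                    reference_annotation = z$reference_annotation)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export per-sample CNV calls as long-format TSV
#'
#' Columns: sample, chrom, start, end, direction, source zone.
#'
#' @param fit An `mgvd` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_cnvs <- function(fit, path) {
  stopifnot(inherits(fit, "mgvd"))
  s <- fit$sample_cnvs
  s$start <- format_bp(s$start)
  s$end <- format_bp(s$end)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
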