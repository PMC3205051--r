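#' Multi-sample aCGH log2-ratio matrix
#'
#' Container for one chromosome's worth of position-sorted probes across N
#' samples.  `values` is an N x M matrix of log2 ratios (raw on input,
#' smoothed after [smooth_probes()]); probe coordinates are 0-based,
#' half-open `[start, end)` as in BED.
#'
#' @param chrom Chromosome label (length 1).
#' @param start,end Integer-valued probe coordinates (bp); `start` strictly
#'   ascending, `start[p] < end[p]`.
#' @param values N x M numeric matrix, one row per sample, one column per
#'   probe; all entries finite.
#' @param samples Character vector of N sample identifiers; defaults to
#'   rownames of `values` or `S1..SN`.
#' @param smoothed Logical provenance flag.
#'
#' @return An object of class `acgh_matrix` with elements `chrom`, `start`,
#'   `end`, `samples`, `values`, `smoothed`.
#' @seealso [read_acgh()], [write_acgh()], [smooth_probes()]
#' @examples
#' m <- acgh_matrix("chr22", c(0, 50), c(50, 100),
#'                  rbind(a = c(0.1, 0.2), b = c(-0.1, 0)))
#' m
#' @export
acgh_matrix <- function(chrom, start, end, values, samples = NULL,
                        smoothed = FALSE) {
  if (length(chrom) != 1L || is.na(chrom))
    stop("'chrom' must be a single label", call. = FALSE)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (n < 1L || m < 1L)
    stop("matrix must have at least one sample and one probe", call. = FALSE)
  if (is.null(samples)) samples <- rownames(values)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n || anyDuplicated(samples))
    stop("'samples' must be ", n, " unique labels", call. = FALSE)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != m || length(end) != m)
    stop("coordinate vectors must match the probe count (", m, ")",
         call. = FALSE)
  if (anyNA(start) || anyNA(end) || !all(is.finite(values)))
    stop("coordinates and log ratios must all be finite", call. = FALSE)
  if (m > 1L && any(diff(start) <= 0))
    stop("probe starts must be strictly ascending (duplicates are invalid)",
         call. = FALSE)
  if (any(start >= end))
    stop("every probe needs start < end", call. = FALSE)
  dimnames(values) <- list(samples, NULL)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 samples = samples, values = values,
                 smoothed = isTRUE(smoothed)),
            class = "acgh_matrix")
}

#' @export
print.acgh_matrix <- function(x, ...) {
  cat(sprintf("aCGH log2-ratio matrix: %d sample(s) x %d probe(s) on %s\n",
              nrow(x$values), ncol(x$values), x$chrom))
  cat(sprintf("  span %s..%s bp, %s\n",
              format(min(x$start), big.mark = ","),
              format(max(x$end), big.mark = ","),
              if (x$smoothed) "smoothed" else "raw"))
  invisible(x)
}

#' @export
dim.acgh_matrix <- function(x) dim(x$values)

#' Read a multi-sample aCGH matrix from a tab-delimited file
#'
#' Expects a header row `chrom start end <sample1> ... <sampleN>` followed by
#' one row per probe.  Rows may arrive unsorted and are re-ordered by start
#' position.  Files holding several chromosomes are split into one matrix
#' per chromosome.  Plain or gzip-compressed files are accepted.
#'
#' @param path File path.
#' @param one_based Set `TRUE` if the file's start coordinates are 1-based
#'   inclusive; they are shifted to the package's 0-based half-open
#'   convention on load.  Default `FALSE` (BED-style input).
#' @return An `acgh_matrix`, or a named list of them if the file covers
#'   several chromosomes.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstart\tend\ts1", "chr22\t100\t150\t0.2"), f)
#' read_acgh(f)
#' @export
read_acgh <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                      check.names = FALSE, colClasses = NA,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed input (", conditionMessage(e), ")",
                             call. = FALSE))
  if (nrow(tab) == 0L || ncol(tab) < 4L)
    stop("need >= 1 probe row and >= 4 columns (chrom, start, end, sample...)",
         call. = FALSE)
  samples <- colnames(tab)[-(1:3)]
  for (j in 2:ncol(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s', data line %d",
                     col[bad[1L]], colnames(tab)[j], bad[1L]), call. = FALSE)
      tab[[j]] <- num
    }
    if (anyNA(tab[[j]]))
      stop(sprintf("missing value in column '%s', data line %d",
                   colnames(tab)[j], which(is.na(tab[[j]]))[1L]),
           call. = FALSE)
  }
  build <- function(sub) {
    o <- order(sub[[2L]])
    start <- sub[[2L]][o] - if (one_based) 1 else 0
    end <- sub[[3L]][o] - if (one_based) 0 else 0
    if (anyDuplicated(start))
      stop("duplicate probe start position on ", sub[[1L]][1L], call. = FALSE)
    acgh_matrix(sub[[1L]][1L], start, end,
                t(as.matrix(sub[o, -(1:3), drop = FALSE])),
                samples = samples, smoothed = FALSE)
  }
  chroms <- unique(tab[[1L]])
  if (length(chroms) == 1L) return(build(tab))
  out <- lapply(chroms, function(cc) build(tab[tab[[1L]] == cc, , drop = FALSE]))
  names(out) <- chroms
  out
}

#' Write a multi-sample aCGH matrix
#'
#' Emits the same tab-delimited dialect [read_acgh()] consumes, at full
#' double precision, so that a write/read round trip reproduces the matrix
#' exactly.
#'
#' @param x An `acgh_matrix`.
#' @param path Output file path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_acgh <- function(x, path) {
  stopifnot(inherits(x, "acgh_matrix"))
  tab <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    check.names = FALSE)
  vals <- as.data.frame(t(x$values))
  colnames(vals) <- x$samples
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(cbind(tab, vals), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Moving-average smoothing of probe log2 ratios
#'
#' Phase 1 of the detector.  Each sample's log2-ratio track is replaced by
#' the mean of a centred window of `window` probes; at chromosome ends the
#' window is truncated to the probes that exist, so the probe count and
#' coordinates never change.  High-resolution oligo arrays have low
#' per-probe signal-to-noise, and an 11-probe window (~550 bp at 50
#' bp/probe) matches the minimum expected CNV size.
#'
#' @param x A raw `acgh_matrix`.
#' @param window Odd window size in probes; `window = 1` is the identity.
#' @return The smoothed `acgh_matrix` (`smoothed = TRUE`).
#' @examples
#' m <- acgh_matrix("chr1", 0:4 * 50, 0:4 * 50 + 50,
#'                  matrix(c(1, 2, 3, 4, 5), 1))
#' smooth_probes(m, 3)$values  # 1.5 2 3 4 4.5
#' @export
smooth_probes <- function(x, window = 11L) {
  stopifnot(inherits(x, "acgh_matrix"))
  if (x$smoothed) stop("matrix is already smoothed", call. = FALSE)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 1", call. = FALSE)
  if (window == 1L) {
    x$smoothed <- TRUE
    return(x)
  }
  m <- ncol(x$values)
  h <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(m) - h, 1L)
  hi <- pmin(seq_len(m) + h, m)
  cnt <- hi - lo + 1L
  sm <- x$values
  for (i in seq_len(nrow(sm))) {
    cs <- c(0, cumsum(x$values[i, ]))
    sm[i, ] <- (cs[hi + 1L] - cs[lo]) / cnt
  }
  x$values <- sm
  x$smoothed <- TRUE
  x
}
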