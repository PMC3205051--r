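#' Pooled centroid statistics
#'
#' The gain/loss flag threshold is anchored to the population of cluster
#' centroids over all segments of the chromosome: a centroid is "out of the
#' neutral position" when its absolute value exceeds mu + sigma of that
#' population.  sigma is the population (not sample) standard deviation.
#'
#' @param centroid_list List of numeric centroid vectors, one per segment
#'   (e.g. `lapply(fits, function(f) f$centroids)`), or a single numeric
#'   vector.
#' @return List with `mu`, `sigma`, and `n` (number of pooled centroids).
#' @export
centroid_stats <- function(centroid_list) {
  cc <- unlist(centroid_list, use.names = FALSE)
  if (length(cc) == 0L)
    stop("no centroids: cluster at least one segment first", call. = FALSE)
  mu <- mean(cc)
  list(mu = mu, sigma = sqrt(mean((cc - mu)^2)), n = length(cc))
}

#' Gain/loss flag of one cluster centroid
#'
#' +1 if the centroid exceeds `mu + sigma`, -1 if it lies below
#' `-(mu + sigma)`, else 0.  Vectorised over centroids.
#'
#' @param centroid Numeric centroid value(s).
#' @param stats Output of [centroid_stats()] (or any list with `mu`,
#'   `sigma`).
#' @return Integer flag(s) in \{-1, 0, 1\}.
#' @examples
#' cluster_flag(c(-3, -4, -2), list(mu = 1, sigma = 0))  # -1 -1 -1
#' @export
cluster_flag <- function(centroid, stats) {
  thr <- stats$mu + stats$sigma
  ifelse(centroid > thr, 1L, ifelse(centroid < -thr, -1L, 0L))
}

#' Flag sum rho of a segment's centroids
#'
#' The weight applied to the cluster-geometry score: the sum of per-cluster
#' flags, in \[-k, k\].  A tight cluster set far from zero reaches |rho| = k
#' even though its pairwise centroid distances are small.
#'
#' @param centroids Numeric vector of k centroids.
#' @param stats Output of [centroid_stats()].
#' @return Integer flag sum.
#' @examples
#' cluster_rho(c(-3, -4, -2), list(mu = 1, sigma = 0))  # -3
#' cluster_rho(c(-3, -4, 2), list(mu = 1, sigma = 0))   # -1
#' @export
cluster_rho <- function(centroids, stats) {
  if (length(centroids) < 1L) stop("need at least one centroid", call. = FALSE)
  sum(cluster_flag(centroids, stats))
}

#' Cluster-geometry score of a segment
#'
#' `f = (1 + |rho|) * sum over unordered centroid pairs of |c_a - c_b|`.
#' The pairwise-distance sum measures how spread the gain/neutral/loss
#' clusters are; the `1 + |rho|` weight rescues segments whose clusters are
#' tight but uniformly displaced from the neutral line (which would
#' otherwise score like a neutral region) and leaves pure-geometry scores
#' untouched when no cluster is flagged.
#'
#' @param fit A [kmeans_1d()] result (or any list with `centroids` and
#'   `assignment`).
#' @param stats Output of [centroid_stats()].
#' @return List: `centroids`, `flags`, `rho`, `base` (pairwise-distance
#'   sum), `score`.
#' @export
score_segment <- function(fit, stats) {
  cc <- fit$centroids
  base <- if (length(cc) < 2L) 0 else {
    d <- outer(cc, cc, "-")
    sum(abs(d[upper.tri(d)]))
  }
  flags <- cluster_flag(cc, stats)
  rho <- sum(flags)
  list(centroids = cc, flags = flags, rho = rho, base = base,
       score = (1 + abs(rho)) * base)
}

#' Gate a scored segment into neutral / candidate / outlier
#'
#' A segment is a candidate CNVZ when its score clears `theta_cnvz`
#' (strict).  Scores at or above `theta_outlier` are trimmed as neutral
#' outliers when the cluster geometry matches a complete loss of the locus
#' in the reference sample -- every cluster displaced to the same side of
#' the neutral line (all flags share one non-zero sign), which inflates
#' every test sample's ratio.  A high score with a mixed geometry (a
#' neutral cluster present) is strong evidence of a genuine zone, not a
#' reference artifact, and stays a candidate.
#'
#' @param score The f value(s) of segment(s).
#' @param flags Integer flag vector of the segment, or a list of flag
#'   vectors parallel to `score`.
#' @param theta_cnvz,theta_outlier Gates, `theta_cnvz < theta_outlier`.
#' @return One of `"neutral"`, `"cnvz_candidate"`, `"outlier_reference_loss"`
#'   per segment.
#' @examples
#' classify_segment(2.4, c(-1L, 0L, 1L), 0.5, 3.5)  # cnvz_candidate
#' classify_segment(5.0, c(1L, 1L, 1L), 0.5, 3.5)   # outlier_reference_loss
#' @export
classify_segment <- function(score, flags, theta_cnvz, theta_outlier) {
  if (!(theta_cnvz < theta_outlier))
    stop("need theta_cnvz < theta_outlier", call. = FALSE)
  if (!is.list(flags)) flags <- list(flags)
  if (length(flags) != length(score))
    stop("'flags' must parallel 'score'", call. = FALSE)
  one_sided <- vapply(flags, function(f)
    length(f) >= 1L && all(f != 0L) && (all(f > 0L) || all(f < 0L)),
    logical(1))
  ifelse(score >= theta_outlier & one_sided, "outlier_reference_loss",
         ifelse(score > theta_cnvz, "cnvz_candidate", "neutral"))
}

#' Merge and prune candidate zones
#'
#' Adjacent candidate spans on the same chromosome are merged while the gap
#' between them is below `merge_gap_bp` (strict `<`); merged zones shorter
#' than `min_cnvz_bp` are then discarded, since calls below the platform's
#' minimum CNV size (~0.5 Kbp) are segmentation shrapnel.  A merged zone
#' inherits the score and flag sum of its highest-scoring constituent.
#'
#' @param candidates data.frame with columns `start`, `end` (half-open bp),
#'   `score`, `rho`, sorted by `start` and non-overlapping; extra columns
#'   are carried from the dominant constituent.  A `members` list-column of
#'   constituent row indices is added.
#' @param merge_gap_bp,min_cnvz_bp Rules as above.
#' @return data.frame of merged zones (possibly 0 rows) with columns of
#'   `candidates` plus `members`.
#' @export
merge_candidates <- function(candidates, merge_gap_bp = 1000,
                             min_cnvz_bp = 500) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$members <- list()
    return(out)
  }
  if (is.unsorted(candidates$start, strictly = FALSE) ||
      any(candidates$start[-1L] < candidates$end[-nrow(candidates)]))
    stop("candidates must be sorted and non-overlapping", call. = FALSE)
  grp <- cumsum(c(1L, as.integer(
    candidates$start[-1L] - candidates$end[-nrow(candidates)] >= merge_gap_bp)))
  pieces <- split(seq_len(nrow(candidates)), grp)
  rows <- lapply(pieces, function(idx) {
    dom <- idx[which.max(candidates$score[idx])]
    row <- candidates[dom, , drop = FALSE]
    row$start <- min(candidates$start[idx])
    row$end <- max(candidates$end[idx])
    row$members <- list(idx)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$end - out$start >= min_cnvz_bp, , drop = FALSE]
}

#' Reference-aberration annotation of a candidate zone
#'
#' Distinguishes the two "obscure call" geometries driven by copy-number
#' aberration of the reference sample.  Case 1 (complete reference loss:
#' every test sample spikes high and the score clears `theta_outlier`) is
#' handled at classification time -- the segment is reported neutral, not as
#' a zone.  Case 2 (heterozygous reference copy number) shows all clusters
#' displaced to one side of the neutral line: every flag shares one sign, so
#' |rho| equals the cluster count.  Such zones are still genuine CNVZs and
#' are emitted with the annotation.
#'
#' @param flags Integer flags of the zone's dominant segment.
#' @return `"obscure_case2_heterozygous_reference"` or `"none"`.
#' @export
annotate_reference <- function(flags) {
  if (length(flags) >= 1L && all(flags != 0L) &&
      (all(flags > 0L) || all(flags < 0L)))
    "obscure_case2_heterozygous_reference"
  else "none"
}

#' Detect common CNV zones across a multi-sample aCGH panel
#'
#' The full four-phase detector: moving-average smoothing, joint
#' segmentation of all samples, per-segment 1-D k-means on the per-sample
#' segment means, and cluster-geometry scoring that gates, merges, prunes
#' and annotates the final CNV zones, plus per-sample CNV extraction.
#'
#' @param x A raw or smoothed `acgh_matrix` (a raw matrix is smoothed with
#'   `cfg$window`), or a path accepted by [read_acgh()].
#' @param cfg An [mgvd_config()].
#' @return An object of class `mgvd` with elements:
#'   \describe{
#'     \item{cnvz}{data.frame of called zones: `chrom`, `start`, `end`,
#'       `name`, `score`, `rho`, `n_samples`, `samples` (comma list with
#'       `+`/`-` direction suffix), `reference_annotation`.}
#'     \item{sample_cnvs}{data.frame of per-sample calls: `sample`, `chrom`,
#'       `start`, `end`, `direction`, `cnvz`.}
#'     \item{segments}{segment table with centroids, flags, `rho`, `score`
#'       and `call` per segment.}
#'     \item{reference_report}{segments suppressed as case-1 reference-loss
#'       outliers.}
#'     \item{centroid_stats}{pooled `mu`/`sigma` used by the flag rule.}
#'     \item{report}{per-phase counts.}
#'     \item{config, chrom, samples, smoothed}{inputs kept for methods.}
#'   }
#' @examples
#' sim <- simulate_acgh(sim_spec(n_samples = 12, n_probes = 800,
#'   zones = data.frame(start_probe = 301, end_probe = 420,
#'                      effect = 0.8, carriers = 0.25),
#'   seed = 7))
#' fit <- mgvd(sim$matrix)
#' fit$cnvz[, c("start", "end", "score", "n_samples")]
#' @export
mgvd <- function(x, cfg = mgvd_config()) {
  if (is.character(x)) x <- read_acgh(x)
  stopifnot(inherits(x, "acgh_matrix"), inherits(cfg, "mgvd_config"))
  raw <- x
  if (!x$smoothed) x <- smooth_probes(x, cfg$window)
  scored <- mgvd_score(x, cfg)
  calls <- mgvd_call(scored, x, cfg)
  structure(list(
    cnvz = calls$cnvz, sample_cnvs = calls$sample_cnvs,
    segments = calls$segments_called,
    reference_report = calls$reference_report,
    report = calls$report,
    centroid_stats = scored$stats,
    config = cfg, chrom = x$chrom, samples = x$samples,
    smoothed = x, raw = raw), class = "mgvd")
}

# Phases 1-3 plus scoring; independent of theta_cnvz so parameter sweeps
# can reuse the result across the theta_cnvz grid.
mgvd_score <- function(x, cfg) {
  seg <- segment_matrix(x, cfg)
  fits <- lapply(seq_len(nrow(seg)), function(i)
    kmeans_1d(segment_means(x, seg$start_index[i], seg$end_index[i]),
              k = cfg$k, max_iter = cfg$kmeans_max_iter,
              tol = cfg$kmeans_tol))
  stats <- centroid_stats(lapply(fits, `[[`, "centroids"))
  sc <- lapply(fits, score_segment, stats = stats)
  seg$centroids <- I(lapply(sc, `[[`, "centroids"))
  seg$flags <- I(lapply(sc, `[[`, "flags"))
  seg$rho <- vapply(sc, `[[`, integer(1), "rho")
  seg$score <- vapply(sc, `[[`, numeric(1), "score")
  list(segments = seg, fits = fits, stats = stats)
}

# Phase 4 gating onward, for a scored segment table.
mgvd_call <- function(scored, x, cfg) {
  seg <- scored$segments
  seg$call <- classify_segment(seg$score, seg$flags,
                               cfg$theta_cnvz, cfg$theta_outlier)
  cand_idx <- which(seg$call == "cnvz_candidate")
  cand <- data.frame(start = seg$start_bp[cand_idx],
                     end = seg$end_bp[cand_idx],
                     score = seg$score[cand_idx],
                     rho = seg$rho[cand_idx],
                     seg_row = cand_idx)
  zones <- merge_candidates(cand, cfg$merge_gap_bp, cfg$min_cnvz_bp)
  fits <- scored$fits
  zone_rows <- list(); cnv_rows <- list()
  if (nrow(zones) > 0L) for (zi in seq_len(nrow(zones))) {
    members <- cand_idx[zones$members[[zi]]]
    dom <- members[which.max(seg$score[members])]
    # participating samples: union over constituents, direction per flag
    per_sample <- list()
    for (si in members) {
      fl <- seg$flags[[si]]
      a <- fits[[si]]$assignment
      hit <- which(fl[a] != 0L)
      if (length(hit))
        per_sample[[length(per_sample) + 1L]] <- data.frame(
          sample = x$samples[hit],
          start = seg$start_bp[si], end = seg$end_bp[si],
          direction = ifelse(fl[a][hit] > 0L, "gain", "loss"))
    }
    cnv <- if (length(per_sample))
      merge_sample_spans(do.call(rbind, per_sample),
                         cfg$merge_gap_bp, cfg$min_cnvz_bp)
    else data.frame(sample = character(), start = numeric(),
                    end = numeric(), direction = character())
    name <- sprintf("CZ_%d", zi)
    parts <- unique(cnv[, c("sample", "direction")])
    parts <- parts[order(match(parts$sample, x$samples)), , drop = FALSE]
    zone_rows[[zi]] <- data.frame(
      chrom = x$chrom, start = zones$start[zi], end = zones$end[zi],
      name = name, score = zones$score[zi], rho = zones$rho[zi],
      n_samples = nrow(parts),
      samples = paste0(parts$sample,
                       ifelse(parts$direction == "gain", "+", "-"),
                       collapse = ","),
      reference_annotation = annotate_reference(seg$flags[[dom]]))
    if (nrow(cnv))
      cnv_rows[[length(cnv_rows) + 1L]] <-
        data.frame(sample = cnv$sample, chrom = x$chrom, start = cnv$start,
                   end = cnv$end, direction = cnv$direction, cnvz = name)
  }
  cnvz <- if (length(zone_rows)) do.call(rbind, zone_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = numeric(), rho = integer(),
               n_samples = integer(), samples = character(),
               reference_annotation = character())
  sample_cnvs <- if (length(cnv_rows)) do.call(rbind, cnv_rows) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), direction = character(), cnvz = character())
  rownames(cnvz) <- rownames(sample_cnvs) <- NULL
  out_idx <- which(seg$call == "outlier_reference_loss")
  reference_report <- data.frame(
    chrom = rep(x$chrom, length(out_idx)),
    start = seg$start_bp[out_idx], end = seg$end_bp[out_idx],
    score = seg$score[out_idx], rho = seg$rho[out_idx],
    annotation = rep("obscure_case1_reference_loss", length(out_idx)))
  list(cnvz = cnvz, sample_cnvs = sample_cnvs, segments_called = seg,
       reference_report = reference_report,
       report = c(n_probes = ncol(x$values), n_samples = nrow(x$values),
                  n_segments = nrow(seg), n_candidates = length(cand_idx),
                  n_outlier_segments = length(out_idx),
                  n_cnvz = nrow(cnvz), n_sample_cnvs = nrow(sample_cnvs)))
}

# Per-sample, per-direction merge/prune using the zone constants.
merge_sample_spans <- function(df, merge_gap_bp, min_cnvz_bp) {
  pieces <- split(df, list(df$sample, df$direction), drop = TRUE)
  out <- lapply(pieces, function(p) {
    p <- p[order(p$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      p$start[-1L] - p$end[-nrow(p)] >= merge_gap_bp)))
    merged <- do.call(rbind, lapply(split(seq_len(nrow(p)), grp), function(i)
      data.frame(sample = p$sample[1L], start = min(p$start[i]),
                 end = max(p$end[i]), direction = p$direction[1L])))
    merged[merged$end - merged$start >= min_cnvz_bp, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample, out$start), , drop = FALSE]
}
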