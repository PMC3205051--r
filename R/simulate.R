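#' Specification of a simulated multi-sample aCGH panel
#'
#' Describes the generative model used for testing: M ordered probes of
#' `probe_len_bp` each, N samples whose baseline log2 ratios are
#' independent Gaussian noise, and planted CNV zones in which a subset of
#' carrier samples is shifted by a constant effect on the log2 scale.  The
#' defaults describe a realistic high-resolution panel: 20 samples, 10,000
#' probes of 50 bp (a 500 Kbp region), noise sd 0.15 (low per-probe SNR,
#' separable after 11-probe averaging), and five zones of 4-12 Kbp with
#' attenuated-aCGH effect sizes 0.6-0.8 carried by 20-35% of samples.
#'
#' @param n_samples,n_probes Panel dimensions.
#' @param probe_len_bp Probe length (bp); probes tile the region end to end.
#' @param noise_sd Gaussian sd of the baseline log2 ratios (>= 0).
#' @param zones data.frame with columns `start_probe`, `end_probe` (1-based,
#'   inclusive), `effect` (signed log2 shift of carriers), `carriers`
#'   (fraction in (0,1\] or integer count of carrier samples).  May have 0
#'   rows.
#' @param reference_scenario `"none"`, or `"case1_complete_loss"` /
#'   `"case2_heterozygous"` applied to the zone `reference_zone`: case 1
#'   (complete loss of the locus in the reference sample) sends every test
#'   sample to a high, sample-to-sample unstable level; case 2
#'   (heterozygous reference copy number) shifts all three cluster levels to
#'   one side of zero by `effect` +/- `case2_spread`.
#' @param reference_zone Row index into `zones` the scenario applies to.
#' @param case1_level,case1_spread Mean and sample-to-sample sd of the
#'   case-1 spike (log2 scale).
#' @param case2_spread Half-distance between adjacent case-2 cluster levels.
#' @param seed Integer RNG seed.
#' @return An object of class `mgvd_sim_spec`.
#' @export
sim_spec <- function(n_samples = 20L, n_probes = 10000L, probe_len_bp = 50L,
                     noise_sd = 0.15,
                     zones = default_zones(n_probes),
                     reference_scenario = c("none", "case1_complete_loss",
                                            "case2_heterozygous"),
                     reference_zone = 1L,
                     case1_level = 2.0, case1_spread = 0.5,
                     case2_spread = 0.2,
                     seed = 1L) {
  reference_scenario <- match.arg(reference_scenario)
  n_samples <- as.integer(n_samples); n_probes <- as.integer(n_probes)
  if (n_samples < 1L || n_probes < 1L || probe_len_bp < 1L)
    stop("panel dimensions must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  zones <- as.data.frame(zones)
  if (nrow(zones)) {
    need <- c("start_probe", "end_probe", "effect", "carriers")
    if (!all(need %in% colnames(zones)))
      stop("'zones' needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(zones$start_probe < 1L) || any(zones$end_probe > n_probes) ||
        any(zones$start_probe > zones$end_probe))
      stop("zones must lie within [1, n_probes]", call. = FALSE)
    if (any(zones$carriers <= 0))
      stop("every zone needs at least one carrier", call. = FALSE)
  }
  if (reference_scenario != "none" &&
      (nrow(zones) < reference_zone || reference_zone < 1L))
    stop("'reference_zone' must index a row of 'zones'", call. = FALSE)
  structure(list(n_samples = n_samples, n_probes = n_probes,
                 probe_len_bp = as.integer(probe_len_bp),
                 noise_sd = noise_sd, zones = zones,
                 reference_scenario = reference_scenario,
                 reference_zone = as.integer(reference_zone),
                 case1_level = case1_level, case1_spread = case1_spread,
                 case2_spread = case2_spread,
                 seed = as.integer(seed)), class = "mgvd_sim_spec")
}

# Default planted-zone layout for a 20 x 10,000-probe panel, scaled to
# other probe counts.  Zone lengths 80-240 probes (4-12 Kbp at 50 bp),
# well separated relative to the 1 Kbp merge radius.
default_zones <- function(n_probes) {
  s <- n_probes / 10000
  z <- data.frame(
    start_probe = round(c(1000, 2800, 4600, 6400, 8200) * s),
    len = round(c(80, 120, 160, 200, 240) * s),
    effect = c(0.8, -0.8, 0.7, -0.7, 0.6),
    carriers = c(0.25, 0.25, 0.30, 0.30, 0.35))
  z$start_probe <- pmax(z$start_probe, 1)
  z$end_probe <- pmin(z$start_probe + pmax(z$len, 1) - 1, n_probes)
  z[, c("start_probe", "end_probe", "effect", "carriers")]
}

#' Simulate a multi-sample aCGH panel with known truth
#'
#' Draws the panel described by a [sim_spec()]: baseline `N(0, noise_sd)`
#' log2 ratios, carrier samples shifted by the zone effect, and optional
#' reference-sample aberration scenarios.  Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param chrom Chromosome label for the generated matrix.
#' @return List of class `mgvd_sim`: `matrix` (raw `acgh_matrix`), `truth`
#'   (data.frame `chrom`/`start`/`end` in bp, the answer set), `carriers`
#'   (data.frame `zone`, `sample`, `direction`), and `spec`.
#' @examples
#' sim <- simulate_acgh(sim_spec(n_samples = 5, n_probes = 300,
#'   zones = data.frame(start_probe = 101, end_probe = 200,
#'                      effect = 0.8, carriers = 2), noise_sd = 0))
#' range(sim$matrix$values[1:2, 101:200])
#' @export
simulate_acgh <- function(spec = sim_spec(), chrom = "chrSim") {
  stopifnot(inherits(spec, "mgvd_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; m <- spec$n_probes
  vals <- matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m)
  zones <- spec$zones
  truth_rows <- list(); carrier_rows <- list()
  if (nrow(zones)) for (zi in seq_len(nrow(zones))) {
    cols <- zones$start_probe[zi]:zones$end_probe[zi]
    scenario <- if (spec$reference_scenario != "none" &&
                    zi == spec$reference_zone) spec$reference_scenario
                else "overt"
    if (scenario == "case1_complete_loss") {
      # complete loss in the reference: every test sample spikes high,
      # with unstable sample-to-sample levels
      levels <- stats::rnorm(n, spec$case1_level, spec$case1_spread)
      vals[, cols] <- vals[, cols] + levels
      carrier_rows[[zi]] <- data.frame(zone = zi, sample = seq_len(n),
                                       direction = "reference_loss_artifact")
    } else if (scenario == "case2_heterozygous") {
      # heterozygous reference: the gain/neutral/loss levels all sit on
      # one side of zero
      grp <- rep_len(1:3, n)[sample.int(n)]
      levels <- zones$effect[zi] + spec$case2_spread * (grp - 2L)
      vals[, cols] <- vals[, cols] + levels
      carrier_rows[[zi]] <- data.frame(zone = zi, sample = seq_len(n),
                                       direction = if (zones$effect[zi] < 0)
                                         "loss" else "gain")
    } else {
      carriers <- zones$carriers[zi]
      n_car <- if (carriers < 1) max(1L, round(carriers * n))
               else as.integer(carriers)
      if (n_car > n) stop("more carriers than samples", call. = FALSE)
      car <- sort(sample.int(n, n_car))
      vals[car, cols] <- vals[car, cols] + zones$effect[zi]
      carrier_rows[[zi]] <- data.frame(zone = zi, sample = car,
                                       direction = if (zones$effect[zi] < 0)
                                         "loss" else "gain")
    }
    truth_rows[[zi]] <- data.frame(
      chrom = chrom,
      start = (zones$start_probe[zi] - 1) * spec$probe_len_bp,
      end = zones$end_probe[zi] * spec$probe_len_bp)
  }
  start <- (seq_len(m) - 1) * spec$probe_len_bp
  mat <- acgh_matrix(chrom, start, start + spec$probe_len_bp, vals)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  carriers <- if (length(carrier_rows)) do.call(rbind, carrier_rows) else
    data.frame(zone = integer(), sample = integer(), direction = character())
  structure(list(matrix = mat, truth = truth, carriers = carriers,
                 spec = spec), class = "mgvd_sim")
}

#' Simulated benchmark panel in the classic 500-probe x 20-sample layout
#'
#' Emulates the shape of the low-resolution simulated benchmark often used
#' for CNV callers: five planted zones jointly covering 92 of 500 probes
#' (~18%) with mixed effect sizes and carrier fractions.  Zone lengths
#' scale proportionally for other probe counts.  This mirrors the printed
#' layout only; it is a synthetic stand-in, not the original published
#' profiles.
#'
#' @param n_samples,n_probes Panel dimensions (`n_probes >= 100`).
#' @param noise_sd Baseline noise sd.
#' @param seed RNG seed.
#' @return An `mgvd_sim` (see [simulate_acgh()]).
#' @export
willenbrock_like <- function(n_samples = 20L, n_probes = 500L,
                             noise_sd = 0.15, seed = 1L) {
  if (n_probes < 100L) stop("'n_probes' must be >= 100", call. = FALSE)
  s <- n_probes / 500
  len <- pmax(round(c(12, 14, 18, 22, 26) * s), 1)
  start <- pmax(round(c(60, 140, 225, 315, 410) * s), 1)
  zones <- data.frame(
    start_probe = start,
    end_probe = pmin(start + len - 1, n_probes),
    effect = c(0.7, -0.7, 0.8, -0.6, 0.6),
    carriers = c(0.35, 0.40, 0.30, 0.45, 0.50))
  simulate_acgh(sim_spec(n_samples = n_samples, n_probes = n_probes,
                         noise_sd = noise_sd, zones = zones, seed = seed))
}
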