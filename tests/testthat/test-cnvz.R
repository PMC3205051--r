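stats1 <- list(mu = 1, sigma = 0)  # mu + sigma = 1, as in the worked examples

test_that("pooled centroid statistics use the population deviation", {
  s <- centroid_stats(list(0))
  expect_equal(s$mu, 0); expect_equal(s$sigma, 0)
  s <- centroid_stats(list(c(-1, 1)))
  expect_equal(s$mu, 0); expect_equal(s$sigma, 1)
  set.seed(9)
  cc <- rnorm(500)
  s <- centroid_stats(split(cc, rep(1:100, each = 5)))
  expect_equal(s$mu, sum(cc) / 500, tolerance = 1e-12)
  expect_equal(s$sigma, sqrt(sum((cc - mean(cc))^2) / 500), tolerance = 1e-12)
  expect_equal(s$n, 500L)
  expect_error(centroid_stats(list()), "no centroids")
})

test_that("flags and their sum rho reproduce the worked centroid sets", {
  expect_identical(cluster_flag(-3, stats1), -1L)
  expect_identical(cluster_flag(2, stats1), 1L)
  expect_identical(cluster_flag(0.5, stats1), 0L)
  expect_identical(cluster_flag(-0.5, stats1), 0L)
  expect_equal(cluster_rho(c(-3, -4, -2), stats1), -3L)
  expect_equal(cluster_rho(c(-3, -4, 2), stats1), -1L)
  expect_equal(cluster_rho(c(0, 0, 0), stats1), 0L)
  expect_error(cluster_rho(numeric(0), stats1), "at least one")
})

test_that("the cluster-geometry score weights pairwise distances by 1+|rho|", {
  fake <- function(cc) list(centroids = cc, assignment = seq_along(cc))
  # coincident clusters score zero regardless of rho
  z <- score_segment(fake(c(-3, -3, -3)), stats1)
  expect_equal(z$base, 0); expect_equal(z$score, 0); expect_equal(z$rho, -3L)
  # symmetric geometry, no flags: pure pairwise sum
  z <- score_segment(fake(c(-0.6, 0, 0.6)), list(mu = 0, sigma = 1))
  expect_equal(z$rho, 0L)
  expect_equal(z$score, 0.6 + 0.6 + 1.2)
  # tight but deeply negative set is amplified past the candidate gate
  z <- score_segment(fake(c(-2.8, -3.0, -3.2)), stats1)
  expect_equal(z$rho, -3L)
  expect_equal(z$base, 0.8, tolerance = 1e-12)
  expect_equal(z$score, 3.2, tolerance = 1e-12)
})

test_that("classification gates candidates strictly between the thresholds", {
  mixed <- c(-1L, 0L, 1L)
  up <- c(1L, 1L, 1L)
  expect_equal(classify_segment(0, mixed, 0.5, 3.5), "neutral")
  expect_equal(classify_segment(0.5, mixed, 0.5, 3.5), "neutral")  # strict
  expect_equal(classify_segment(2.4, mixed, 0.5, 3.5), "cnvz_candidate")
  expect_equal(classify_segment(5.0, up, 0.5, 3.5), "outlier_reference_loss")
  # one-sided geometry below the outlier gate stays a candidate
  expect_equal(classify_segment(3.2, c(-1L, -1L, -1L), 0.5, 3.5),
               "cnvz_candidate")
  # extreme score with a neutral cluster present is not a reference artifact
  expect_equal(classify_segment(5.0, mixed, 0.5, 3.5), "cnvz_candidate")
  expect_error(classify_segment(1, mixed, 3.5, 0.5), "theta_cnvz")
})

test_that("candidate counts respond monotonically to both gates", {
  set.seed(14)
  scores <- runif(200, 0, 6)
  flags <- lapply(1:200, function(i) sample(c(-1L, 0L, 1L), 3, replace = TRUE))
  ncand <- function(tc, to)
    sum(classify_segment(scores, flags, tc, to) == "cnvz_candidate")
  for (tc in c(0.2, 0.5, 1, 2))
    expect_gte(ncand(tc, 3.5), ncand(tc + 0.5, 3.5))
  for (to in c(2, 3, 4, 5))
    expect_lte(ncand(0.5, to), ncand(0.5, to + 1))
})

test_that("candidate zones merge below 1 Kbp gaps and prune below 0.5 Kbp", {
  cand <- data.frame(start = c(100, 1400), end = c(600, 2000),
                     score = c(1.2, 0.8), rho = c(1L, 1L))
  z <- merge_candidates(cand, 1000, 500)
  expect_equal(nrow(z), 1L)
  expect_equal(c(z$start, z$end), c(100, 2000))
  expect_equal(z$score, 1.2)  # dominant constituent
  # a gap of exactly 1 Kbp is not merged (strict <)
  cand2 <- data.frame(start = c(100, 1600), end = c(600, 2200),
                      score = c(1.2, 0.8), rho = c(1L, 1L))
  z2 <- merge_candidates(cand2, 1000, 500)
  expect_equal(nrow(z2), 2L)
  # a lone 400 bp span is discarded
  z3 <- merge_candidates(data.frame(start = 100, end = 500,
                                    score = 2, rho = 0L), 1000, 500)
  expect_equal(nrow(z3), 0L)
  expect_error(merge_candidates(data.frame(start = c(500, 100),
                                           end = c(700, 300),
                                           score = 1:2, rho = c(0L, 0L))),
               "sorted")
})

test_that("reference annotation flags one-sided cluster geometry", {
  expect_equal(annotate_reference(c(-1L, -1L, -1L)),
               "obscure_case2_heterozygous_reference")
  expect_equal(annotate_reference(c(1L, 1L)),
               "obscure_case2_heterozygous_reference")
  expect_equal(annotate_reference(c(-1L, 0L, 1L)), "none")
  expect_equal(annotate_reference(c(0L, 0L, 0L)), "none")
})

test_that("a constant matrix yields no zones", {
  m <- acgh_matrix("chr1", (0:199) * 50, (1:200) * 50, matrix(0.1, 4, 200))
  fit <- mgvd(m)
  expect_equal(nrow(fit$cnvz), 0L)
  expect_equal(nrow(fit$sample_cnvs), 0L)
})

test_that("a noise-free planted gain is recovered to within one window", {
  zones <- data.frame(start_probe = 101, end_probe = 200,
                      effect = 0.8, carriers = 5)
  sim <- simulate_acgh(sim_spec(n_samples = 20, n_probes = 400,
                                noise_sd = 0, zones = zones, seed = 2))
  fit <- mgvd(sim$matrix)
  expect_equal(nrow(fit$cnvz), 1L)
  w_bp <- 11 * 50
  expect_lte(abs(fit$cnvz$start - sim$truth$start), w_bp)
  expect_lte(abs(fit$cnvz$end - sim$truth$end), w_bp)
  cnv <- fit$sample_cnvs
  expect_equal(nrow(cnv), 5L)
  expect_true(all(cnv$direction == "gain"))
  expect_setequal(cnv$sample, paste0("S", sim$carriers$sample))
  expect_true(all(cnv$start >= fit$cnvz$start & cnv$end <= fit$cnvz$end))
})

test_that("balanced gain and loss clusters yield per-sample calls both ways", {
  # 6 samples: 2 loss, 2 neutral, 2 gain in one zone -> rho 0, geometry only
  vals <- matrix(0, 6, 300)
  vals[1:2, 121:180] <- -0.8
  vals[5:6, 121:180] <- 0.8
  set.seed(6)
  vals <- vals + rnorm(length(vals), 0, 0.02)
  m <- acgh_matrix("chr1", (0:299) * 50, (1:300) * 50, vals)
  fit <- mgvd(m)
  expect_equal(nrow(fit$cnvz), 1L)
  expect_equal(fit$cnvz$rho, 0L)
  expect_equal(fit$cnvz$n_samples, 4L)
  cnv <- fit$sample_cnvs
  expect_setequal(cnv$sample[cnv$direction == "loss"], c("S1", "S2"))
  expect_setequal(cnv$sample[cnv$direction == "gain"], c("S5", "S6"))
})

test_that("detection is deterministic and sample-permutation equivariant", {
  sim <- simulate_acgh(sim_spec(n_samples = 10, n_probes = 1500,
    zones = data.frame(start_probe = 601, end_probe = 720,
                       effect = 0.8, carriers = 3), seed = 33))
  fit1 <- mgvd(sim$matrix)
  fit2 <- mgvd(sim$matrix)
  expect_equal(fit1$cnvz, fit2$cnvz)
  expect_equal(fit1$sample_cnvs, fit2$sample_cnvs)
  # permute rows: zones identical, ownership permuted
  p <- sample(10)
  mp <- sim$matrix
  mp$values <- mp$values[p, ]
  mp$samples <- mp$samples[p]
  dimnames(mp$values) <- list(mp$samples, NULL)
  fitp <- mgvd(mp)
  expect_equal(fitp$cnvz[, c("start", "end", "score", "rho", "n_samples")],
               fit1$cnvz[, c("start", "end", "score", "rho", "n_samples")])
  expect_setequal(fitp$sample_cnvs$sample, fit1$sample_cnvs$sample)
})

test_that("zone output is sorted, separated, and respects the size floor", {
  for (s in 1:5) {
    sim <- simulate_acgh(sim_spec(n_samples = 12, n_probes = 3000, seed = s))
    fit <- mgvd(sim$matrix)
    z <- fit$cnvz
    if (nrow(z) >= 1) {
      expect_true(all(z$end - z$start >= 500))
      expect_false(is.unsorted(z$start))
    }
    if (nrow(z) > 1)
      expect_true(all(z$start[-1] - z$end[-nrow(z)] >= 1000))
    cnv <- fit$sample_cnvs
    if (nrow(cnv)) {
      expect_true(all(cnv$end - cnv$start >= 500))
      for (i in seq_len(nrow(cnv))) {
        zi <- match(cnv$cnvz[i], z$name)
        expect_true(cnv$start[i] >= z$start[zi] && cnv$end[i] <= z$end[zi])
      }
    }
  }
})

test_that("zone BED and per-sample TSV exports are well formed", {
  sim <- simulate_acgh(sim_spec(n_samples = 10, n_probes = 1500,
    zones = data.frame(start_probe = 601, end_probe = 720,
                       effect = 0.8, carriers = 3), seed = 33))
  fit <- mgvd(sim$matrix)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_cnvz_bed(fit, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_length(lines, nrow(fit$cnvz))
  expect_length(lines[[1]], 10L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sample_cnvs(fit, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(fit$sample_cnvs))
  expect_equal(tab$sample, fit$sample_cnvs$sample)
})
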