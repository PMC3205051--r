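test_that("correlation and distance of the worked adjacent-vector examples", {
  v1 <- c(0, 1, 0, 1, 0, 1); w1 <- c(0, 10, 0, 10, 0, 10)
  v2 <- c(4, 5, 4, 5, 4, 5); w2 <- c(5, 4, 5, 4, 5, 4)
  expect_identical(pcc(v1, w1), 1)
  expect_identical(pcc(v2, w2), -1)
  expect_equal(manhattan_dist(v1, w1), 27)
  expect_equal(manhattan_dist(v2, w2), 6)
  expect_equal(manhattan_dist(v1, v1), 0)
  # self-correlation of any non-constant vector
  set.seed(3)
  v <- rnorm(8)
  expect_equal(pcc(v, v), 1)
  # zero-variance convention
  expect_identical(pcc(rep(1, 4), c(1, 2, 3, 4)), 0)
  expect_error(pcc(1:3, 1:4), "length")
  expect_error(pcc(1, 2), "2 samples")
  expect_error(manhattan_dist(1:3, 1:4), "length")
})

test_that("pcc matches the stats::cor oracle on 1000 random pairs", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(2:20, 1)
    v <- rnorm(n); w <- rnorm(n)
    r <- pcc(v, w)
    expect_equal(r, pcc_oracle(v, w), tolerance = 1e-12)
    expect_lte(abs(r), 1)
  }
})

test_that("manhattan_dist is symmetric and satisfies the triangle inequality", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(1:15, 1)
    a <- rnorm(n); b <- rnorm(n); cc <- rnorm(n)
    expect_equal(manhattan_dist(a, b), manhattan_dist(b, a))
    expect_lte(manhattan_dist(a, cc),
               manhattan_dist(a, b) + manhattan_dist(b, cc) + 1e-12)
  }
})

test_that("breakpoint rule reproduces the worked verdicts", {
  # synchronized but large jump: correlation 1, distance 27 -> break
  expect_true(is_breakpoint(c(0, 1, 0, 1, 0, 1), c(0, 10, 0, 10, 0, 10),
                            theta_pcc = 0.8, theta_dist = 0.075))
  # anti-correlated unit wiggle with small actual distance -> no break
  expect_false(is_breakpoint(c(4, 5, 4, 5, 4, 5), c(5, 4, 5, 4, 5, 4),
                             theta_pcc = 0.8, theta_dist = 1.5))
  # identical non-constant vectors never break
  v <- c(0.1, 0.4, -0.2, 0.3)
  expect_false(is_breakpoint(v, v, 0.99, 1e-6))
  # flat-to-flat adjacency is governed by the distance test alone
  expect_false(is_breakpoint(rep(0.1, 5), rep(0.1, 5), 0.8, 0.075))
  expect_true(is_breakpoint(rep(0.1, 5), rep(0.9, 5), 0.8, 0.075))
  # one-sided flat adjacency: some samples moved, consistency broken
  expect_true(is_breakpoint(rep(0, 4), c(0.02, 0, 0, 0), 0.8, 0.075))
})

test_that("a constant matrix yields a single segment", {
  m <- acgh_matrix("chr1", (0:9) * 50, (1:10) * 50,
                   matrix(0.1, 3, 10), smoothed = TRUE)
  seg <- segment_matrix(m, mgvd_config())
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_index, 1L)
  expect_equal(seg$end_index, 10L)
})

test_that("a degenerate correlation threshold breaks every adjacency", {
  m <- random_panel(n = 4, m = 30, seed = 21)
  m$smoothed <- TRUE  # treat the noise directly as the smoothed signal
  cfg <- mgvd_config(theta_pcc = 1, theta_dist = 1e9)
  seg <- segment_matrix(m, cfg)
  expect_equal(nrow(seg), 30L)
  expect_true(all(seg$n_probes == 1L))
})

test_that("a planted cross-sample step yields exactly one breakpoint", {
  # samples 1-2 step from 0 to 1 after probe 5; samples 3-4 flat but distinct
  vals <- rbind(c(rep(0, 5), rep(1, 4)),
                c(rep(0, 5), rep(1, 4)),
                rep(0.1, 9),
                rep(0.2, 9))
  m <- acgh_matrix("chr1", (0:8) * 50, (1:9) * 50, vals, smoothed = TRUE)
  seg <- segment_matrix(m, mgvd_config())
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$start_index, c(1L, 6L))
  expect_equal(seg$end_index, c(5L, 9L))
})

test_that("segments always tile the probe index range", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:8, 1); m <- sample(2:80, 1)
    x <- random_panel(n = n, m = m, seed = 31 + i)
    x <- smooth_probes(x, sample(c(1, 3, 5, 11), 1))
    cfg <- mgvd_config(theta_pcc = runif(1), theta_dist = runif(1, 0.01, 1))
    seg <- segment_matrix(x, cfg)
    expect_true(all(seg$n_probes >= 1L))
    expect_equal(seg$start_index[1], 1L)
    expect_equal(seg$end_index[nrow(seg)], m)
    if (nrow(seg) > 1)
      expect_equal(seg$start_index[-1], seg$end_index[-nrow(seg)] + 1L)
  }
})

test_that("segment_matrix agrees with the scalar breakpoint rule", {
  x <- smooth_probes(random_panel(n = 5, m = 50, seed = 41), 5)
  cfg <- mgvd_config(theta_pcc = 0.9, theta_dist = 0.05)
  seg <- segment_matrix(x, cfg)
  manual <- which(vapply(1:49, function(i)
    is_breakpoint(x$values[, i], x$values[, i + 1],
                  cfg$theta_pcc, cfg$theta_dist), logical(1))) + 1L
  expect_equal(seg$start_index, c(1L, manual))
})

test_that("threshold changes move breakpoint counts monotonically", {
  x <- smooth_probes(random_panel(n = 4, m = 100, sd = 0.3, seed = 51), 3)
  nseg <- function(tp, td)
    nrow(segment_matrix(x, mgvd_config(theta_pcc = tp, theta_dist = td)))
  for (td in c(0.02, 0.05, 0.1))
    expect_gte(nseg(0.8, td), nseg(0.8, td * 2))
  for (tp in c(0.9, 0.6, 0.3))
    expect_gte(nseg(tp, 0.05), nseg(tp - 0.2, 0.05))
})

test_that("segmentation rejects unsmoothed input and single samples", {
  raw <- random_panel(n = 3, m = 10)
  expect_error(segment_matrix(raw), "smoothed")
  one <- smooth_probes(random_panel(n = 1, m = 10), 3)
  expect_error(segment_matrix(one), "2 samples")
})
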