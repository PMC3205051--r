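# Independent oracles used to cross-check the implementation.

# Pearson correlation through stats::cor (independent of pcc()'s own
# centered-sum arithmetic).
pcc_oracle <- function(v, w) {
  if (stats::sd(v) == 0 || stats::sd(w) == 0) return(0)
  stats::cor(v, w)
}

# Globally optimal k-cluster within-SS by exhaustive enumeration of
# contiguous partitions of the sorted values (1-D optimal clusters are
# contiguous).  Only feasible for small n; independent of the package's
# dynamic program.
enum_inertia <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  k <- min(k, length(unique(v)))
  if (n <= k) return(0)
  ss <- function(x) sum((x - mean(x))^2)
  if (k == 1L) return(ss(v))
  best <- Inf
  cuts <- utils::combn(n - 1L, k - 1L)
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, ci], n)
    tot <- 0
    for (j in seq_len(k)) tot <- tot + ss(v[(b[j] + 1L):b[j + 1L]])
    if (tot < best) best <- tot
  }
  best
}

# Base-pair confusion by brute-force per-bp membership over an integer span.
bp_confusion_oracle <- function(calls, truth, span) {
  pos <- seq.int(span[1], span[2] - 1L)
  inset <- function(df) {
    hit <- rep(FALSE, length(pos))
    if (nrow(df)) for (i in seq_len(nrow(df)))
      hit <- hit | (pos >= df$start[i] & pos < df$end[i])
    hit
  }
  a <- inset(as.data.frame(calls))
  b <- inset(as.data.frame(truth))
  list(tp = sum(a & b), fp = sum(a & !b), fn = sum(!a & b), tn = sum(!a & !b))
}

# Small noisy panel for property-style tests.
random_panel <- function(n = 6, m = 120, sd = 0.2, seed = 1) {
  set.seed(seed)
  start <- (seq_len(m) - 1) * 50
  acgh_matrix("chrT", start, start + 50,
              matrix(stats::rnorm(n * m, 0, sd), n, m))
}
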