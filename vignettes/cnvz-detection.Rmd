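---
title: "Detecting common CNV zones across multi-sample aCGH panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting common CNV zones across multi-sample aCGH panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgvd)
```

## The problem

Array CGH measures, probe by probe, the log2 ratio of test-sample DNA
abundance against a reference sample.  On high-resolution oligo platforms
(one probe per ~50 bp) each probe is individually too noisy to segment a
single sample reliably, but a panel of samples measured on the same design
carries a strong joint signal: at a locus where some samples share a gain
or loss, the cross-sample profile changes shape in a way that no amount of
per-probe noise mimics.  `mgvd` exploits this by calling **CNV zones**
jointly from the whole panel — a zone is a locus where the panel's
log2-ratio behaviour splits into gain/neutral/loss groups — and only then
assigning per-sample CNVs.  This is different from, and complementary to,
building consensus regions out of single-sample calls.

## The model, phase by phase

### Smoothing

Each sample's track is smoothed with a centred moving average.  The
default window of **11 probes (~550 bp)** matches the minimum CNV size the
platform can support, so true events survive smoothing while per-probe
noise is attenuated by √11.  At chromosome ends the window is truncated to
the probes that exist: the alternative (padding or dropping edge probes)
either fabricates data or changes the coordinate system, and a shortened
mean is still an unbiased local estimate.  `window = 1` is the exact
identity, and constant signals are fixed points, which the tests assert.

### Joint segmentation

With `V[i]` the N-vector of smoothed ratios at probe `i`, position `i+1`
starts a new segment when

```
|PCC(V[i], V[i+1])| < theta_pcc   OR   MD(V[i], V[i+1]) / N > theta_dist
```

Pearson correlation catches samples breaking rank; it is insensitive to a
synchronized shift of the whole panel (correlation stays 1 when every
sample jumps together), so the Manhattan-distance clause catches those.
MD is divided by N so `theta_dist` reads as a *mean per-sample log2 jump*
and is comparable across panel sizes; the default 0.075 sits far above the
jump two overlapping 11-probe windows can produce by noise alone at
realistic noise levels.

Two numerical conventions matter here:

* **Zero variance.**  A position where every sample is equal has undefined
  correlation; `pcc()` returns 0.  In the breakpoint rule, a *flat-to-flat*
  adjacency is decided by the distance clause alone (so an exactly constant
  stretch is one segment, not M singletons), while a *flat-to-varying*
  adjacency keeps the returned 0 — some samples started moving, which is
  precisely a consistency break.  Only this reading is consistent with
  both degenerate limits: a constant matrix segments as one segment, and a
  noise-free planted zone is delimited exactly at its smoothing ramp.
* **Threshold sidedness.**  Both clauses are strict, so `theta_pcc = 1`
  breaks everything non-collinear and a huge `theta_dist` defers entirely
  to the correlation.

Raising `theta_dist` or lowering `theta_pcc` can only remove breakpoints;
this monotonicity is property-tested.

### Clustering

Each segment is reduced to one scalar per sample — the per-sample mean —
so a sample belongs to exactly one cluster.  The three-cluster model
(k = 3) encodes the gain/neutral/loss prior; extreme states fold into gain
or loss, so no model selection over k is needed.

`kmeans_1d()` solves the one-dimensional problem **exactly**: optimal 1-D
clusters are contiguous runs of the sorted values, so a dynamic program
over split points finds the global within-sum-of-squares optimum in
O(kN²).  We chose this over classical Lloyd iteration (which is retained
as `method = "lloyd"`, deterministically seeded at the minimum, median and
maximum) after measuring that Lloyd misses the global optimum on roughly a
third of small random instances — an avoidable source of irreproducibility
and score noise.  Fewer than k distinct values reduce k with a flag rather
than erroring, which also covers panels with N < 3.

### Scoring and calling

Let μ and σ be the mean and *population* standard deviation of every
centroid of every segment on the chromosome — a self-calibrating summary
of what "neutral" looks like in this dataset.  Each cluster gets a flag:
+1 if its centroid exceeds μ+σ, −1 below −(μ+σ), else 0; ρ is the flag
sum.  The segment score is

```
f(CLU) = (1 + |rho|) * sum over unordered pairs |c_a - c_b|
```

The pairwise-distance sum measures cluster spread (a balanced
gain/neutral/loss geometry scores on spread alone, ρ = 0 leaves it
unweighted), while the `1 + |rho|` factor rescues tight-but-displaced
geometries — three clusters all at strongly negative ratios score low on
spread yet are plainly a shared loss.  Segments with `f > theta_cnvz`
become candidates; adjacent candidates separated by less than 1 Kbp merge
(strict `<`), and merged zones shorter than 0.5 Kbp — the platform's
approximate minimum CNV size — are discarded (strict `<`; both constants
are configuration values, and a merged zone inherits the score of its
strongest constituent).

### Reference-sample aberrations

The reference sample is not guaranteed neutral, which produces "obscure"
calls:

* **Case 1 — complete reference loss.**  Every test sample's ratio spikes
  high and unstable; the cluster geometry is extreme *and one-sided*.
  Segments with `f >= theta_outlier` (default 3.5) **and** all flags
  sharing one sign are suppressed as neutral outliers and surfaced in a
  side report rather than as zones.
* **Case 2 — heterozygous reference copy number.**  All three cluster
  levels sit on one side of zero but below the outlier gate; these are
  genuine zones and are emitted with the case-2 annotation
  (operationalised, like case 1, as all flags sharing one non-zero sign).
* Covert calls (test and reference aberrant identically) are invisible to
  any ratio-only method and are out of scope.

A design note: an earlier revision gated the outlier trim on the score
alone.  Combined with exact clustering this misfired — the globally
optimal partition of a strong minority-gain segment often splits the
*carrier* cluster, doubling |ρ| and pushing a genuine zone's f past the
gate — suppressing about a third of planted zones in the recovery
benchmark below.  Restricting the trim to the one-sided geometry that a
complete reference loss actually produces removed the misfire without
affecting case-1 behaviour; this is the package's own reading of an
otherwise underdetermined rule.

## Evaluation harness

Calls are scored against a truth set per **base pair** over the probed
span `[min start, max end)`: TP/FP/FN/TN partition the span exactly
(integer arithmetic, overlapping records coalesced first), from which
FDR = FP/(FP+TP), sensitivity = TP/(TP+FN) and
F1 = 2·(1−FDR)·sens/((1−FDR)+sens) follow.  With no calls, FDR is 0 by
convention and flagged; an empty truth set is an error rather than a
silent NaN.  The TN universe is the probed span, not the chromosome —
without probes there is no assay and no meaningful negative.
`parameter_sweep()` runs the 9 × 10 default grid (θ_dist 0.025–0.225 by
0.025; θ_cnvz 0.05–1.4 by 0.15); phases 1–3 and scoring depend only on
θ_dist, so they are computed once per θ_dist value and shared across the
θ_cnvz grid — caching is exact, not approximate.

## What the simulator does and does not emulate

`simulate_acgh()` draws i.i.d. Gaussian baseline noise (default
sd 0.15, giving realistically low per-probe SNR that separates after
11-probe averaging), adds a constant log2 shift to carrier samples inside
planted zones, and implements both obscure-call scenarios (case 1:
all-sample high unstable spike; case 2: one-sided three-level shift).
Default effects of 0.6–0.8 reflect the attenuated shifts real aCGH
intensity compression produces for single-copy events, with 20–35% carrier
fractions and 4–12 Kbp zones on a 20 × 10,000-probe panel.
`willenbrock_like()` mirrors the published low-resolution benchmark's
*layout* — five zones jointly covering 92 of 500 probes — not its data.

Deliberately **not** modelled: GC/wave baseline artifacts, probe-specific
response, spatial noise correlation, dye bias, and heterogeneous per-carrier
effects.  A green recovery test therefore establishes that the algorithm
recovers planted low-SNR zones under white noise — not that it is robust
to structured array artifacts, which real panels exhibit and which
per-chromosome parameter tuning is meant to absorb.

```{r}
sim <- simulate_acgh(sim_spec(seed = 42))
fit <- mgvd(sim$matrix)
fit
span <- c(min(sim$matrix$start), max(sim$matrix$end))
unlist(cnv_metrics(basepair_confusion(fit$cnvz, sim$truth, span)))
```

Residual base-pair FDR under defaults is boundary overshoot: when an edge
correlation dip narrowly misses θ_PCC the zone's delimiting breakpoint
lands at the nearest chance dip outside, extending the called span.  The
sweep's lower θ_dist settings tighten boundaries on small panels, which is
exactly how the two parameters are meant to be tuned per chromosome.

```{r}
plot(fit)
```

## Known limitations

* Boundaries are resolved to roughly the smoothing window; sub-window
  precision would need a raw-signal refinement step the method does not
  define.
* The score gate θ_outlier assumes case-1 artifacts are rarer and more
  extreme than true zones; a chromosome where most loci are aberrant
  violates the μ+σ calibration.
* Zones carried by a single sample compete with noise in a k = 3 geometry
  and are only found when the effect is large; the method is aimed at
  *common* CNVs.
* One chromosome per run; multi-chromosome inputs are split on load and
  tuned separately by design.
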