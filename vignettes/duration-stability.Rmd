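---
title: "Scanning-duration stability of fNIRS connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning-duration stability of fNIRS connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirsconn` asks a design question of resting-state optical neuroimaging: how
much scanning time does a functional connectome need before its
connectivity pattern and graph-theory summaries are stable within a session
and reproducible between repeated runs? This vignette is the package's own
account of the models it implements, the assumptions behind them, and the
choices made where the methods literature leaves the design open.

## 1. The synthetic world

Because the package must be verifiable without recordings, its first-class
module is a generator whose ground truth is known exactly.

**Signal model.** A subject-run record is a channels × samples matrix of
hemoglobin concentration changes. White Gaussian noise is given a target
channel covariance by Cholesky factorization and then passed through the
*same* zero-phase band-pass filter the preprocessing stage uses, so the
generator and the pipeline agree on what "in-band" means. The filter is
applied twice in the generator: a single order-3 zero-phase pass leaves
about 4% of white-noise power in the transition skirts, which a Welch
periodogram (with its own window leakage) reads as ~6% out-of-band; the
double pass puts >99% of true power inside 0.01–0.1 Hz, so the stated
spectral property of the clean signal ("essentially all power in-band")
holds under the same estimator the classifier uses. Because every channel
passes through the same linear filter, the zero-lag correlation structure
of the target covariance is preserved exactly.

**Ground-truth connectomes.** Two constructors are provided.
`make_modular_covariance()` builds the familiar equal-block community
matrix (within-module correlation `within_r`, between-module `between_r`,
optional jitter, PSD projection); it exercises clustering and local
efficiency non-trivially, but its true *nodal* profile is nearly flat — all
nodes in equal blocks are exchangeable. `make_hub_covariance()` builds a
two-factor model, S_ij = a_i a_j + b² [same module], with the global-factor
loading a_i rising smoothly across channels (default 0.45–0.85). That hub
gradient gives nodes genuinely different efficiencies and betweenness, which
matters whenever a test asks whether *nodal maps* replicate between runs: in
an exchangeable-node world there is no between-node signal to replicate and
between-run map correlations are ~0 at every duration, not because the
pipeline fails but because the world is degenerate. The factor model also
keeps every FC entry positive, mirroring unregressed resting-state optical
FC — which is what makes thresholding feasible up to 0.5 sparsity (see §4).

**Reliability calculus.** Test–retest reliability is injected through a
single subject-level scalar, the network coupling
λ_sr = clamp(λ₀ + b_s + w_sr), with b_s ~ N(0, σ²_b) shared by a subject's
runs and w_sr ~ N(0, σ²_w) independent per run; the run's generating matrix
is (1−λ_sr) I + λ_sr Σ. The implied intraclass correlation is
σ²_b/(σ²_b + σ²_w) exactly (up to rare clamping), so ICC recovery can be
checked at any cohort size through `simulate_reliability_scalars()` without
simulating signals. Defaults σ_b = 0.12, σ_w = 0.06 put the true ICC at 0.8
— the "excellent" band that real whole-head FC reliability studies report.

**Artifacts.** Four classes, each with an amplitude in units of the clean
signal's standard deviation (all zero ⇒ clean cohort): motion spikes
(Poisson events, exponential decay, amplitude 5, ~2/min), slow U-shaped
drift (quadratic, amplitude 1.5, ~30% of channels), cardiac (1 Hz) and
respiratory (0.3 Hz) oscillations with common phase and per-channel gain
(amplitude 0.6), and a global superficial component with near-uniform
spatial loading (amplitude 1.5). Two realism decisions matter for ICA:

* all spikes in a run share one spatial profile — the cap's motion
  signature — so motion forms a single rank-1 source a 30-component model
  can isolate; with independent per-event channels, ~20 rank-1 transients
  would provably smear across most components;
* the global component is a Mayer-wave-like amplitude-modulated oscillation
  (0.07–0.1 Hz). A temporally Gaussian in-band global source is
  information-theoretically invisible to ICA (any rotation of a Gaussian
  subspace is equivalent); the quasi-oscillatory source is sub-Gaussian and
  separable, and its detection then rests on the spatial criterion, which
  is the point of that criterion.

No noise amplitudes are reported for the emulated acquisition anywhere, so
these defaults are free parameters chosen once for plausibility, not
estimates of any study's noise levels.

## 2. Preprocessing

**MBLL.** Optical-density changes at two wavelengths map linearly to
ΔHbO/ΔHbR through the 2×2 extinction system scaled by source–detector
separation (3.2 cm) and differential pathlength factor (6.0). The forward
and inverse models share one matrix, so the round trip is exact to
numerical precision; an ill-conditioned extinction pair warns, a singular
one fails.

**PCA + ICA.** The channel matrix is reduced to the smallest principal
subspace holding 99% of variance, whitened, and unmixed by symmetric
FastICA (tanh contrast, fixed internal seed, bounded restarts). Tolerance
defaults follow the reference implementation (1e-4); when a near-Gaussian
component pair cycles without settling — a known fixed-point oscillation —
the best-effort unmixing is returned with a diagnostic warning rather than
an error, as the reference implementations do, and only gross
non-convergence fails. Reconstruction subtracts the *noise* components from
the original data (equivalently: zeroes their mixing columns while leaving
signal components and the 1% PCA residual untouched), so an all-signal
labelling reproduces the input exactly.

**Noise criteria.** A component is noise iff any of three flags fires; all
thresholds are config-exposed and all criteria are invariant to component
sign and scale.

* *Temporal* — sudden jumps, spike showers, or a slow U/inverted-U shape.
  Jumps are measured as the one-sample change in robust SDs of the
  component: an in-band signal sampled well above its band can move at most
  ~2π f_max/f_s of its amplitude per sample (<0.5 SD at the defaults),
  while a motion transient moves by its full amplitude. The
  first-difference z-score against the MAD of the differences — the obvious
  alternative — was rejected after calibration: FastICA components of
  band-limited data are intrinsically heavy-tailed (sample kurtosis 10–50
  on artifact-free cohorts, since the effective sample count of a 0.01–0.1
  Hz process over 600 s is ~100 and ICA picks the most non-Gaussian
  projections), so that statistic flags 10–25% of clean components. With
  the amplitude-referenced statistic (jump > 3 robust SDs/sample, shower
  > 5 above-1-SD samples/min, quadratic R² > 0.8), artifact-free cohorts
  classify with zero false positives while planted spikes and drifts are
  caught.
* *Spectral* — Welch dominant frequency outside 0.01–0.1 Hz (half-bin
  slack at the edges; undefined and false, with a warning, for components
  shorter than two spectral windows).
* *Spatial* — normalized non-central kurtosis of the mixing column,
  κ = n Σw⁴/(Σw²)², is 1 for perfectly uniform loading and n for a focal
  one. The dispersive threshold is κ < 1.5: a mathematically uniform map
  attains 1.0 exactly, but any jittered or estimated global map sits at
  1.0–1.2 while module-confined sources sit at ≥ n/module-size ≈ 3, so 1.5
  separates the classes; a threshold of 1.0 can never fire. At the default
  amplitudes the planted global component is flagged in ≥90% of runs;
  misses occur when ICA splits it across components, which the
  channel-count of a whole-head montage (46) keeps rare.

**Filtering and binning.** Zero-phase order-3 Butterworth (bilinear-design,
forward–backward with odd-reflection padding sized to the slowest pole's
settling), stop-band ≥20 dB at half/twice the band edges, then truncation
into prefix windows of 60, 90, …, 600 s anchored at the first sample —
prefixes, not sliding windows, because the question is "how much scanning
time", so every bin represents a recording stopped at that moment. The
chromophore analyzed defaults to HbO (the higher-SNR species); HbR flows
through the identical code path.

## 3. Connectivity

Pearson correlation over the window, and maximum lagged cross-correlation:
the correlation of the overlapping segments at every integer lag in
[−L, +L], with means and variances recomputed on the overlap (full-series
denominators can push |r| beyond 1), the value being the maximum and
`best_lag` its argmax, ties resolved to the smallest |lag|, negative first
— which makes the matrix symmetric with an antisymmetric lag matrix. The
printed definition of the lagged estimator ranges delays over the entire
series length; that is degenerate at extreme lags (vanishing overlap) and
asymmetric, so the implementation caps lags at L = 20 s by default (an
upper bound on plausible hemodynamic transit delays) with at least 50%
overlap, both configurable. L = 0 reduces exactly to Pearson. No Fisher
transform is applied anywhere; all analyses use raw r.

## 4. Network metrics

FC matrices are thresholded by sparsity (edges kept / edges possible) over
the grid 0.17–0.50 in steps of 0.01 — 34 thresholds, the small-world range
for 46-node brain graphs. Edges are the top round(s·M) correlations in
descending order; negative correlations rank last and selecting one is an
error (a report of how many positives exist), ties at the cutoff break by
(row, column) order so thresholding is deterministic. Edge counts round
half-away-from-zero (round(0.17·1035) = 176); floor rounding is a config
switch.

Binary distances are hop counts (matrix BFS); weighted edges have length
1/weight, so stronger correlations are shorter. Nodal efficiency, global
efficiency (its mean), clustering (triangle counting; weighted uses the
Onnela geometric-mean intensity normalized by the maximum weight), local
efficiency (mean global efficiency of neighbor-induced subgraphs, nodes
with <2 neighbors contributing 0), and betweenness follow the standard
formulations. One convention required a decision: normalizing betweenness
by (n−1)(n−2) is stated alongside worked values that imply *unordered*
pair counting (a 3-node path's middle node scores 0.5); the package adopts
that convention throughout (range [0, 0.5]), and the star-center value is
0.5 accordingly. Unreachable pairs contribute zero efficiency and are
excluded from path-count ratios. Each metric's curve over the grid is
summarized by its trapezoidal AUC. Betweenness and weighted distances are
delegated to igraph (Brandes' algorithm); everything downstream of the FC
matrix is deterministic.

## 5. Evaluation

**Stability** compares each duration's map (FC upper triangle in fixed
order, or a nodal AUC vector) with the same run's 600-s reference map by
Pearson correlation, per subject, summarized as group mean ± sd; global
metric AUCs are compared by paired t-test (degenerate cases defined
explicitly: all-zero differences give t = 0, p = 1). At 600 s the
comparison is with itself: r = 1 and t = 0 exactly, a structural identity
the tests assert.

**Reproducibility and reliability** correlate run-1 and run-2 maps per
subject (global AUCs across subjects), and compute the one-way
intraclass correlation ICC = (MS_b − MS_w)/(MS_b + (k−1) MS_w) from the
between/within-subject mean squares. For maps the ICC is computed per
element and averaged. Negative ICCs are reported as computed and banded
"low"; the qualitative bands are the Cicchetti-style cut-offs 0.4/0.6/0.75
(configurable). p-values are unadjusted throughout — the analysis is
descriptive, not confirmatory.

**What a green convergence test establishes — and what it does not.** On a
stationary clean cohort, within-run stability r rises monotonically (within
a Monte-Carlo tolerance of 3 standard errors of the per-subject paired
differences) to exactly 1, and between-run correlations rise with duration.
They do *not* approach 1 at 600 s: the sampling noise of a correlation
estimated from a 0.01–0.1 Hz process over 600 s is O(0.1–0.2) per edge
(effective dof ≈ 2·bandwidth·T ≈ 100), so between-run map correlations
plateau far below unity — which is also where real two-run whole-head
cohorts sit. The degenerate limit (zero within-subject variance ⇒ ICC 1) is
asserted on the coupling scalar, where it is exact. The generator also does
not emulate eyes-open/closed state effects, non-stationary arousal drift,
optode-coupling changes between runs, or photon-transport physics; a green
suite certifies the pipeline's statistics, not those phenomena.

## 6. Numerical and scale choices

* Master seed + counter-derived per-(subject, run, purpose) streams: cohorts
  are bit-reproducible and order-independent; all derived seeds stay below
  2³¹.
* Test-scale profile: 5 Hz sampling (the band top is 0.1 Hz, so 25×
  oversampling carries no information for these analyses), 46 channels,
  600 s — keeps the full suite within minutes while preserving every
  structural cardinality (19 bins, 34 thresholds, 1035 edges).
* The oracle suite re-implements every metric by brute force (triple-loop
  Floyd–Warshall, exhaustive shortest-path enumeration, explicit triangle
  counting, two-pass correlation, aov-based ICC) and requires agreement to
  1e-12 (binary) / 1e-9 (weighted) on hundreds of random graphs.

## 7. Known limitations

* ICA rejection is blind source separation: it cannot remove noise that is
  spatially and spectrally indistinguishable from signal (in particular, a
  temporally Gaussian in-band global process), and its component count is
  bounded by the PCA subspace.
* Short-separation regression and adaptive filtering — alternatives that
  require dedicated hardware channels — are out of scope by design.
* The weighted local-efficiency variant (global efficiency of the
  neighbor subgraph under 1/weight lengths) is one of several in use;
  it and the Onnela clustering are config-documented choices, not the only
  defensible ones.
* Dynamic (sliding-window) connectivity, partial correlation, coherence,
  small-world indices, modularity and hub classification are outside the
  package's scope.
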