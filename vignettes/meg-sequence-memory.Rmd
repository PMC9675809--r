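---
title: "Models and methods: simulating and analyzing MEG auditory sequence recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analyzing MEG auditory sequence recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what the
synthetic-data generator emulates, how each analysis stage is defined, which
parameters matter, and where the honest limitations lie. Nothing here states
an empirical result that the test suite does not itself compute.

# The paradigm being simulated

An old/new auditory recognition experiment: subjects memorize a tonal
musical piece and an atonal counterpart (every pitch class displaced by one
or two semitones, uniformly across octaves, which preserves rhythm, contour
and the positional recurrence of tones while destroying the tonal center).
During recognition they hear 160 five-tone excerpts — per piece, 40
memorized and 40 novel — each 1250 ms (250 ms per tone) preceded by a
100 ms baseline, and respond old/new. MEG is recorded continuously (150 Hz
in the simulator); behavior is accuracy (of 40) and reaction time, plus a
1–7 familiarity rating per subject.

# Stimulus predictability: the n-gram model

Melodic expectation is modeled by a bounded-order n-gram with additive
smoothing: `p(e | ctx) = (count(ctx, e) + γ) / (count(ctx) + γ|A|)` over a
finite alphabet `A` of MIDI pitches. Per-tone information content is
`IC = log2(1/p)` (bits) and the context entropy is the expected IC over the
alphabet. `H = 0` when one continuation is certain and `log2 |A|` under
uniformity; both identities, and the equality of `entropy()` with an
explicit enumeration loop, are property-tested over a thousand random
models.

Design choices: events are pitches only (the stimuli have constant rhythm
by construction); contexts shorter than the model order at a sequence start
back off to the longest available context (standard n-gram practice); the
default order is 2 with γ = 1; a toy corpus of diatonic random walks makes
IC/H computable offline. Consequently the *absolute* IC/H values depend on
this toy corpus and are not comparable to values from large multi-viewpoint
models trained on real repertoires — only the tonal/atonal *difference*
under a fixed model is meaningful here.

# The synthetic cohort

## Geometry and forward model

The head is a homogeneous conducting sphere (radius 90 mm). Sensor sites
lie on a Fibonacci spiral over the upper hemisphere of a 102 mm shell; each
site carries a magnetometer (radial field, T) and an orthogonal
planar-gradiometer pair (finite differences of the radial component over a
17 mm baseline, T/m). 102 sites give the familiar 306-channel layout. A 2D
sensor layout for cluster statistics is built by azimuthal-equidistant
projection snapped to the smallest collision-free grid.

The forward model is the analytic external field of a current dipole in a
conducting sphere. Radial moments are externally silent, so the lead field
has two tangential columns per dipole; a dipole at the sphere center is
silent entirely (documented degeneracy). Sources live on a cubic grid
(8 mm at full scale) restricted to the sphere interior, with named
spherical ROI patches standing in for anatomy. The patches are deliberately
generous: each represents a multi-area territory (the lateral patches the
peri-sylvian auditory network, the medial patches a contiguous
hippocampal–cingulate memory block), sized to the spatial resolution the
beamformer actually achieves on this geometry, and their centers sit
slightly inward of the territory they name because minimum-variance
localization on a sphere is biased inward.

## Ground-truth effects

Each effect activates a handful of dipoles (`n_focus`, default 3–4) at the
core of its ROI patch — compact generators, not whole coherent patches,
because a perfectly coherent extended patch is exactly the correlated
source configuration a minimum-variance beamformer cancels at its own
location. Dipoles of a patch share a locally coherent orientation (one base
angle, 0.3 rad dispersion), carry per-dipole latency offsets (sd 40 ms) and
per-trial log-normal amplitude jitter (sd 0.4), so they are strongly but
not perfectly correlated, as in cortex.

The default ground truth encodes the dissociation the analysis chain is
designed to recover: every condition evokes a fast-band damped 5.5 Hz
response to each tone in both auditory patches (30 nA·m); memorized tonal
trials add a slow-band envelope over tone windows 3–5 in the cingulate
patch (60, 72, 72 nA·m — deep sources need larger moments to be visible);
memorized atonal trials add a slow-band envelope across all five windows in
the right auditory patch (35 nA·m). Slow envelopes are Hann-smoothed
per-window boxes with a smooth 200 ms offset tail (an abrupt offset rings
through the high-pass filter).

## Ongoing activity and noise

One hundred background dipoles per subject carry unit-variance AR(1)
(φ = 0.97, low-pass) time courses at 45 nA·m. This background serves two
purposes at once: it is the realistic "ongoing brain activity" that
dominates the data covariance — which is the regime in which a beamformer
behaves like a well-conditioned linear inverse rather than cancelling its
own targets — and it sets the additive noise floor of the evoked averages.
The effect amplitudes above were chosen once so that the sensor-level
effect-to-background ratio is near 1.5, i.e. single-trial effects are
buried but ~35-trial averages have SNR around 8, the classical
evoked-response regime. Sensor noise is iid Gaussian per channel type
(200 fT magnetometers, 8 pT/m gradiometers). Between-subject amplitude
variability is log-normal with sd 0.1: small enough that the additive noise
floor, not multiplicative scaling, dominates the between-subject CV — the
group t-statistic then grades with effect strength across voxels instead of
saturating at `sqrt(n)/CV` everywhere the effect leaks.

## Behavior

Per-subject accuracy follows a logit-normal-binomial: condition means
(34.34, 34.41, 30.98, 34.51 of 40, memorized-atonal hardest) shifted by a
subject ability term (logit sd 1.0), which reproduces the overdispersion of
real cohorts (binomial alone gives SD ≈ 2.3; the published cohorts show
≈ 5–6). Reaction times are log-normal around condition means (1735–1879 ms)
with a subject-level offset (sd 0.14) and trial-level sd 0.25. Familiarity
ratings are drawn from a skewed 1–7 distribution (most listeners know a
famous prelude only casually).

# Preprocessing

Band-pass filtering is zero-phase (forward–backward) Butterworth, order 4
per pass, realized as a high-pass/low-pass cascade: a direct
transfer-function band-pass at 0.1–1 Hz with 150 Hz sampling is numerically
unstable (pole radius > 1), while the cascade is stable and keeps passband
amplitude within 0.5%. Edges are handled by odd-reflection padding of three
time constants of the slowest edge. Epochs run −100…+1250 ms with the
convention `floor((tmax − tmin)·fs) + 1` samples (203 at 150 Hz) and
per-trial baseline correction over the 100 ms pre-onset window; analyses
use correctly answered trials only. Planar pairs are combined by
root-sum-square, giving non-negative combined-gradiometer signals.

# Cluster-based Monte-Carlo significance

Mass-univariate tests are binarized (0/1) at the voxel/channel alpha and
split by direction. Clusters are connected components under
orthogonal-neighbor adjacency (4-connectivity in 2D, 6 in 3D; time counts
as one orthogonal axis), the conservative standard choice; diagonal
adjacency is available. The null distribution re-places the observed number
of ones uniformly over the valid cells and records the maximum cluster size
per permutation — permuting the binarized map itself, not subject labels.
A cluster is significant iff its size strictly exceeds the empirical
`(1 − α)` quantile of the null; p-values use the +1 correction.

Two properties delimit what this buys you. On maps whose ones arise from
independent per-cell tests the procedure is calibrated — the family-wise
error on null data stays at or below its nominal level (tested over 200
null cohorts). On *spatially smooth* maps — e.g. beamformed source maps,
whose leakage correlates neighboring voxels — the uniform-replacement null
underestimates how large chance clusters can be, and the procedure becomes
anticonservative: small spurious clusters can reach "significance" under a
true null. This is a property of the published procedure itself, inherited
deliberately; interpret isolated small source clusters with caution and
rely on the direction/window/territory structure of an effect rather than
any single cluster.

# Source analysis

## Beamformer

The data covariance is the sample covariance over concatenated epoch
samples plus diagonal loading `λ = 0.05 × mean(diag)`. The scalar LCMV
filter per dipole uses the power-maximizing tangential orientation (the
eigenvector of the smaller eigenvalue of `L' C⁻¹ L`) with unit-gain
minimum-variance weights; its unit-gain contract, exact noiseless
amplitude round trip (≤ 1%), and localization within one grid step
(two at 20 dB SNR) are tested. The scalar orientation is the right tool
when the source of interest contributes appreciably to the covariance (as
in localization tasks). For *mapping weak evoked effects* the covariance is
dominated by ongoing activity, the orientation estimate is steered by
geometry rather than by the effect, and the projection of the true moment
onto the chosen axis is essentially arbitrary per dipole. The pipeline
therefore maps with the *vector* variant — an independent unit-gain filter
per tangential component — and compares **window-mean component-norm
magnitudes**, which are orientation- and sign-free.

Two further conventions matter. First, reconstructions used for mapping are
unit-noise-gain normalized (`w / ‖w‖`): unit-gain weight norms grow toward
the sphere center, and without normalization magnitude statistics inflate
with depth. Physical amplitudes (A·m) are available by leaving
normalization off. Second, the first-level contrast is the plain difference
of condition means; a data-driven "align signs so the mean time course has
a positive peak" step is available (`align = "peak"`) but not default,
because any alignment statistic computed from the same data as the contrast
couples to it — with unequal condition variances the aligned contrast
acquires a positive bias at every voxel, which we verified produces
amplitude-independent pseudo-clusters.

## Two-level window statistics

Per subject, band and piece: condition means are reconstructed, and the
memorized-vs-novel contrast is taken on window-mean magnitudes over the
five 250 ms tone windows. At the group level a one-sample t-test across
subjects per dipole and window is binarized at the voxel alpha (0.05;
sub-average-then-test), split by direction, and submitted to a 3D spatial
cluster MCS at the Bonferroni-adjusted alpha `0.01 / (5 windows × 2 bands)
= 0.001`. The tonal-vs-atonal contrast applies the same machinery to the
per-subject difference of memorized window magnitudes (voxel alpha 0.01);
the slow-vs-fast band contrast z-scores window magnitudes within band per
subject first, so a global band gain cannot masquerade as an effect.
Familiarity analyses correlate ratings with window magnitudes per dipole
(Pearson), binarize at 0.05 and use the 95% max-cluster rule.

Cluster tables report size `k`, the per-label voxel tally, the majority
label and its fraction, and the permutation p-value. When judging whether
a cluster "is" in a territory, the informative comparison is the plurality
among *labeled* member voxels: clusters always include a point-spread halo
over unlabeled filler voxels of the synthetic head, so the raw fraction of
any one label is diluted by construction.

# Behavioral statistics

Accuracy and RT are each analyzed with a classical one-way between-groups
ANOVA over the four conditions, treating subject-by-condition cells as
independent observations — with N subjects this yields df (3, 4N − 4),
matching the F(3, 280) layout of 71-subject cohorts. Post-hoc pairwise
two-sample t-tests (pooled variance) are judged against the adjusted alpha
0.05/4 = 0.0125; the divisor 4 reproduces the adjusted alpha printed in the
study design this simulator emulates, although six pairs exist — a
deliberate fidelity choice, documented here because textbook Bonferroni
would divide by 6. Repeated measures treated as independent groups is a
statistical caveat of that design, preserved as-is.

# Scales, runtimes and determinism

Desk-scale defaults (64 sensor sites, 12 mm grid, 12 subjects, 1000
permutations) complete a full `run_all()` in minutes on one CPU;
`paper_scale = TRUE` selects 102 sites, 8 mm and 71 subjects. The validation
suite uses deliberately reduced sizes chosen as the smallest problems that
still exercise every code path: 16–48 sensor sites, 16–24 mm grids, 8
subjects and 10 seeded cohorts for the end-to-end dissociation, 200
replicates for error-rate calibration, 10,000 permutations against
exhaustive enumeration on ≤ 12-cell maps. Every random stage draws its seed
deterministically from a master seed (`spawn_seeds`), so identical
configurations produce hash-identical output tables.

# Known limitations

* Spherical geometry, analytic single-sphere forward model, no anatomy or
  co-registration: ROI labels are synthetic territories, not atlases. The
  lead-field contract allows an overlapping-spheres variant to be swapped
  in.
* The cluster permutation null ignores spatial autocorrelation (see above);
  it is calibrated for independent-cell maps only.
* Deep medial sources are recovered as diffuse territories; their cluster
  boundaries are not anatomically sharp at desk-scale sensor counts, which
  is why effect territories rather than exact voxel sets are the unit of
  interpretation.
* The n-gram stimulus model quantifies relative, not absolute, melodic
  complexity (toy corpus).
* The simulator emits artifact-free data: no environmental interference,
  eye/cardiac artifacts, head movement, or their corrections — passing
  tests validate the statistics chain, not robustness to artifacts.
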