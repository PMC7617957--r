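---
title: "Methods: lineage-resolved quantification of barrel-cortex circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-resolved quantification of barrel-cortex circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the measurement models implemented in
`barrelcircuit`, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate,
and the numerical choices made where the underlying procedures leave the
design open. It states no empirical result that the test suite does not
itself compute.

## The scientific problem

Layer 4 (L4) of mouse primary somatosensory cortex is organised into
barrels, one per whisker. First-order thalamus (VPM) relays single-whisker
information into the barrels; higher-order thalamus (POm) carries
multi-whisker and contextual signals into the septa and L4. Individual L4
excitatory neurons differ in how selective they are for their principal
whisker (PW) versus adjacent whiskers (AW), and one candidate source of this
heterogeneity is developmental lineage: neurons derived from intermediate
progenitors (IP-derived, labelled in vivo via a Tα1-promoter optotagging
strategy) versus neurons of other progenitor origin (OP-derived). The
package quantifies that relationship at every level at which it is measured:
laminar spiking in vivo, paired intracellular recording in vitro, barrel
histology, and sensory-evoked plasticity.

## Electrophysiology processing

**Band splitting.** The multiunit band is 300–6000 Hz and the LFP band is
<300 Hz with a 50 Hz notch. The implementation applies order-4 Butterworth
*power* responses (the magnitude a forward–backward Butterworth would
apply) in the frequency domain, giving exactly zero phase delay. Zero phase
matters because every downstream statistic (CSD sink latency, response
latency, optotag latency) is a latency. A time-domain forward–backward
filter would need a filter-design library not available in this
environment; the frequency-domain filter matches its magnitude response and
its zero-phase property, and the tests verify the stated attenuations
(≥40 dB at 1 kHz in the LFP band, ≥20 dB at 50 Hz) directly from spectra.

**Multiunit detection.** The noise scale is the normalised median absolute
deviation, `sigma = median(|x − median(x)|)/0.6745`, robust to the spikes
themselves. Events are negative crossings of `−k·sigma` with a refractory
lockout. Defaults `k = 5` and 1 ms lockout are standard robust-threshold
practice; the underlying method is cited without a multiplier, so both are
exposed as arguments. A constant trace is an error (zero MAD would otherwise
make the detector infinitely sensitive).

**CSD and layers.** The CSD is the central second spatial difference of the
LFP across channels divided by the squared spacing; edge channels are
excluded because the stencil is undefined there. No spatial smoothing is
applied by default (an optional 3-channel Hamming kernel exists behind a
flag). A sink is a local minimum. "The shortest-latency evoked sink is L4"
needs an operational onset: per channel, the sink latency is the first
post-deflection time the CSD crosses 30% of the global minimum; the channel
with the smallest latency is L4, ties going to the larger-amplitude sink.
The 30% fraction is a free choice; it is exposed as `sink_frac` and the
recovery tests pass across planted-sink sessions regardless of its exact
value in a broad range.

**Unit classification.** Trough-to-peak time at least 0.5 ms defines
regular-spiking; the boundary value is assigned to RS (the criterion is
stated as a separation value, not a strict inequality — one tie-break had
to be chosen, and it is documented here and in the function). Optotagging
requires mean light-evoked latency below 5 ms *and* reliability of at least
0.5 across light trials within a 10 ms window (the in vivo pulse duration).
The reliability floor operationalises "reliable, short-latency"; 0.5 is a
package default, not a claim of the source procedure, and is configurable.

## Whisker tuning

Spontaneous activity is computed trial by trial over a 500 ms pre-stimulus
baseline (the subtraction is specified trial-by-trial; the window length is
a package default) and subtracted as `rate × window` from each evoked
count. The selectivity index is

> SI = R_PW / (R_PW + R_AW)

where R is the *cumulative* spontaneous-subtracted count over all trials —
summed, not averaged per trial, which is the reading of "cumulative" that
is robust to zero-count trials (the per-trial-average alternative is
available behind `per_trial_average` and gives identical SI with equal
trial counts). Negative cumulative counts are clipped to zero before the
ratio so SI stays in [0, 1]; SI is undefined and flagged when both sums are
non-positive. Train SI sums four 50 ms windows anchored at each deflection
onset of the 10 Hz train. Response latency is the 1 ms bin of the first
spike 5–20 ms post-deflection, per trial, averaged over contributing
trials.

## Paired-recording input bias

EPSPs are measured on the average of 10–40 sweeps: baseline = mean of the
50 ms before light onset; amplitude = peak of the baseline-subtracted trace
1–50 ms after light; onset = the last upward crossing of baseline + 2 SD
before the peak, linearly interpolated. The 2 SD onset criterion and the
50 ms search window are package defaults (both unstated in the source
procedure, both configurable). Responses are gated as monosynaptic when
onset ≤ 6 ms, bracketing the reported 3–4 ms thalamocortical delays with
headroom. The bias index is `A_IP/(A_IP + A_OP)` — the only convention in
which 0.5 means equal input and which matches the reported directions
(below 0.5 for VPM input to IP-derived cells, above 0.5 for POm). It
satisfies `bias(a, b) + bias(b, a) = 1`.

Intrinsic properties come from current-step protocols: RMP is the mean
pre-stimulus voltage of the 0 pA sweeps; spikes are upward crossings of
dV/dt ≥ 20 mV/ms (an automated stand-in for manual threshold placement,
configurable); amplitude is peak minus threshold; frequency and ISIs are
per step.

## Histology

**Straightening.** Each point maps to (s, d): arc length of its orthogonal
foot on the reference polyline (drawn along the L4/L5 boundary) and signed
normal distance. |d| equals the Euclidean point-to-polyline distance
exactly — the transform preserves relative soma position while flattening
the layers. In image coordinates (y down, pia above the reference), the
pia side is negative d. The image variant inverse-maps a regular (s, d)
grid with bilinear interpolation.

**Barrel detection.** The straightened L4 intensity profile is smoothed
(Gaussian, σ = 5 µm default), thresholded at the midpoint between the 10th
and 90th intensity percentiles (robust septal floor and barrel plateau),
and maximal runs above threshold wider than 30 µm become barrels, with
boundaries interpolated at the threshold crossings. The percentile midpoint
makes detection invariant to affine intensity rescaling, which the tests
assert.

**Soma index.** 1 at a barrel centre, 0 at a septal midpoint, linear in
between: `clip(|s − m| / |c − m|, 0, 1)` with c the nearest centre and m
the nearest septal midpoint; beyond the outer barrels the outer half-gap is
mirrored. Only the two anchors are defined by the source procedure; the
linear ramp is the package's choice (a cosine ramp is selectable).

**Dendritic overlap.** Segments are clipped against each barrel region
(tangential interval × L4 band) with exact parametric (Liang–Barsky)
clipping — no rasterisation — so per-barrel percentages plus the outside
percentage sum to 100 within 1e-6 by construction, and results do not
depend on any sampling resolution. The principal barrel holds the majority
of dendrite; "the next closest barrel" is resolved as the non-principal
barrel whose centre is nearest the soma (second-highest overlap is
selectable; the two coincide on the synthetic fixtures). Neurons with under
5% of dendritic length in every barrel are flagged excluded.

**Intensity measures.** Soma MPI uses a fixed-radius disk mask (5 µm
default) in place of manual outlines. The Lhx2 ratio requires exactly three
qualifying neighbours — fewer is an error, not a two-neighbour fallback.
ROI expression fraction thresholds each section with Otsu's method and
reports suprathreshold-in-ROI over all suprathreshold pixels, per section
and averaged.

## Plasticity

The RWS schedule is fixed by the protocol's printed numbers: 100 pre and
100 post deflections at 0.1 Hz and 8 Hz × 60 s = 480 induction events every
125 ms. The statistic is `delta = 100 × post_rate/pre_rate` on
spontaneous-subtracted rates over 250 ms multi-whisker windows — a ratio,
not a percent change, because the no-induction control value (~106%) is
only consistent with the ratio convention. Delta is undefined and flagged
when the baseline rate is not positive. Session-level rates feed a paired t
test across animals.

## Statistics

Welch's t is used wherever "t test" is named for two groups (no equal
variance assumption); the automatic mode gates on Shapiro-Wilk at α = 0.05
and otherwise uses the Mann-Whitney U test with tie correction, all tests
two-sided. Dunn's post hoc z tests on mean ranks follow a significant
Kruskal-Wallis, Bonferroni-adjusted over the tested pairs (no correction is
named in the source; Bonferroni is the conservative default). IQRs use
linear-interpolation quantiles (R type 7), stated in every report. The test
suite pins all p-values to an independent reference implementation (SciPy
1.17, values frozen) at 1e-6 and calibrates each test's type-I error by
simulation.

## The synthetic world

The generators state a world in which every downstream estimator has
closed-form truth:

- **Evoked spiking** is Bernoulli per deflection (at most one evoked spike,
  probability `p_pw` or `p_aw`, latency truncated-normal in (0, 50] ms) on
  top of homogeneous Poisson background. True SI is exactly
  `p_pw/(p_pw + p_aw)`. This deliberately ignores bursting, adaptation, and
  rate-modulated evoked responses — a green SI-recovery test establishes
  estimator correctness under the stated model, not robustness to every
  physiological firing pattern.
- **Laminar LFP** is synthesized from a target CSD (Gaussian sink in
  channel and time) by discrete double cumulative summation × spacing², the
  exact inverse of the central-difference CSD, so the noiseless round trip
  is machine-precision exact. It is not a biophysical forward model: no
  volume conduction, no return sources.
- **EPSP sweeps** use an alpha kernel `a·x·exp(1 − x)`, `x = (t − t0)/τ`,
  whose peak equals `a` exactly; the kernel form is a package choice (the
  source states none) with one realistic rise/decay parameter. Planted
  amplitudes keep mean peaks below 3 mV, the low-amplitude monosynaptic
  regime. Default noise 0.1 mV, 20 sweeps, onset 3.5 ms, τ = 4 ms.
- **Barrel images** (1 µm/px, 16-bit range) render a quadratically curved
  L4 band stamped along the layer normals, so barrel territories are
  defined in the arc-length frame in which they are analysed; intensities
  default to 9000/4000/1500 (barrel/septum/background) with additive
  Gaussian noise. Blob texture, vasculature, and z-structure are not
  emulated. Somata and simple straight dendrites carry construction truth.
- **Plasticity counts** are Poisson with means
  `(rate + spont) × window`, post replacing `rate` by `g × rate`; `g = 1`
  encodes no plasticity and the expected delta is `100·g`. Defaults
  (pre_rate 40 Hz, spont 5 Hz, 100 trials, 250 ms) sit in the range of the
  reported session rates.

Where neither the source procedures nor the build contract states a value
(latency spreads, noise levels, evoked-latency distribution), the defaults
above were chosen once as field-typical and are not tuned against test
outcomes.

## Numerical and engineering choices

- Filtering is O(n log n) FFT-based and length-preserving; reapplication is
  idempotent on in-band content up to the transition band.
- All file formats are plain text (TSV tables, whitespace SWC, JSON
  configs, TSV image matrices standing in for single-channel TIFF, which
  has no reader in the dependency budget).
- Generators seed the RNG from their parameter object; identical parameters
  are bit-identical, which the suite asserts for every generator.
- Degenerate inputs error loudly rather than silently degrade: zero-MAD
  traces, flat CSDs, flat intensity profiles, zero-length dendrites,
  both-zero bias amplitudes, zero-variance t tests, fewer than three Lhx2
  neighbours.

## Known limitations

- No spike sorting: the package consumes sorted units or detects multiunit
  events; optotagging of single units assumes the spike times it is given.
- The straightening transform is 2-D; z is carried through SWC files but
  ignored in overlap geometry (the analysed preparations are single
  z-planes).
- Barrel regions are tangential intervals extruded over the L4 band — the
  row geometry of the analysed sections — not general 2-D polygons.
- The Mann-Whitney implementation is the asymptotic tie-corrected test;
  exact small-sample p-values are not used (group sizes in the target
  designs are ≥ 4 and the reference values are matched at 1e-6 against the
  same convention).
- Dunn's post hoc joint selectivity at small n and moderate shifts is
  limited by the Bonferroni adjustment; the suite asserts the property at
  effect sizes where the stated world supports it.
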