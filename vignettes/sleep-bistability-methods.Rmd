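---
title: "Methods: scoring sleep-state bistability and simulating its circuit basis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring sleep-state bistability and simulating its circuit basis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepswitch)
```

This vignette explains the models behind the package, the assumptions they
make, the parameters that matter, and the design decisions taken where the
underlying method left genuine freedom. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. State-space scoring of NREM/REM intermediary sleep

### The embedding

Each 5-s EEG epoch is reduced to a point in two dimensions:

* `x` — log10 of the ratio of spectral power at 7–9 Hz to power at 1–9 Hz
  (a theta-dominance index; because the numerator band is a subset of the
  denominator band, `x <= 0` always);
* `y` — log10 of total 1–19 Hz power.

Powers are band sums of a single rectangular-window periodogram per epoch
(`compute_band_powers()`); sums are taken before the log. Both coordinates
are smoothed with a centred 5-epoch moving average whose window shrinks
symmetrically at the recording edges (widths 1, 3, 5), so no epochs are
truncated. Epochs with non-finite samples, all-zero power, or zero 1–9 Hz
power are flagged invalid and excluded from every downstream step — never
interpolated. Absolute power is used by default; `relative = TRUE`
normalises per-epoch to total 1–33 Hz power (the `x` ratio is unaffected).

### Boundaries from trajectory intersections

The scoring method rests on one dynamical assumption: within a stable sleep
state the trajectory is confined by its generating circuit and therefore
reverses and self-intersects over short spans, while in transitionary space
it is directed and avoids looping. `find_intersections()` tests every
non-adjacent segment pair that fits inside a 5-epoch moving window for a
proper crossing (orientation test; touching endpoints and collinear overlap
do not count) and reports each crossing pair once. The four segment
endpoints of each crossing are assigned to the NREM or REM cluster by their
manual 3-stage label (wake points are discarded — the assignment rule is
our choice; the method's source describes labelled clusters without stating
one). Each cluster is trimmed **once** of points farther than
mean + 5 SD of the centroid distance and wrapped in a convex envelope
(`grDevices::chull`). Overlapping envelopes are a hard error: the control
period does not support separable clusters.

A statistical note on the trim: the largest attainable z-score among *n*
points is `(n-1)/sqrt(n)`, so the rule cannot flag anything in clusters of
fewer than ~27 points; it is effective exactly in the regime it is meant
for, dense clusters with a few extreme points.

NRt space is the convex envelope of all between-boundary points belonging
to complete NREM-to-REM transitions of the control period (exit the NREM
polygon, later dwell in the REM polygon, no intervening wake), minus the
state-polygon interiors. A concave (alpha-shape) alternative was considered
and rejected for determinism; the convex envelope is reproducible and
parameter-free.

### The six scoring rules

Sleep epochs whose trajectory leaves the state polygons are relabelled `t`
when the whole excursion satisfies:

1. preceded by two consecutive in-boundary sleep epochs;
2. a switch to the other sleep state counts only after two consecutive
   in-boundary epochs there — consequently a *single* in-polygon epoch
   neither starts nor ends a state, and isolated one-epoch dips inside an
   excursion belong to the excursion (this structural reading stabilises
   segmentation when a polygon is tight);
3. excursions ending in an arousal or returning to their origin must last
   at least two epochs;
4. t-bouts separated by manual arousals of at most three epochs are one
   bout (applied at the bout-statistics level; the arousal epochs keep
   their W label, so wake abundance is bit-identical between 3- and
   4-stage scoring);
5. excursions from NREM must head toward REM: the mean `x` of the
   excursion's epochs inside NRt space must lie on the REM side of the
   last in-boundary epoch, with "REM side" read off the fitted cluster
   centroids (orientation-free; an explicit sign override exists). An
   earlier formalisation using only the first two excursion epochs proved
   noise-dominated — excursions often begin with one or two cluster-edge
   epochs whose displacement is a coin flip — and was replaced;
6. the excursion must pass **through** NRt space: at least two consecutive
   epochs inside the transition-trajectory envelope. Requiring *every*
   point inside proved wrong in closed-loop testing: whenever a state
   polygon under-covers its cluster, an excursion run acquires a few
   out-of-envelope epochs at its edges and an all-points rule rejects the
   entire genuine excursion.

Wake epochs are never relabelled; epochs with invalid coordinates keep
their 3-stage label. Boundaries fitted on a control period are reused
unchanged to score any later period of the same recording.

Bout statistics (`bout_stats()`): bouts are maximal same-label runs; each
t-bout's origin is the sleep state immediately before it; NRt density per
origin is bouts per minute spent in the origin state (undefined — `NA`,
never infinite — when the origin state has zero time); NRt percentage uses
total sleep time (N + R + t epochs); REM bouts split at 15 epochs (75 s)
into short and long; "long" NRt bouts are those of three epochs or more.

## 2. The flip-flop switch

### Model

Nondimensional LIF neurons (threshold 1, rest 0, time in membrane time
constants):

`dv_i/dt = -v_i + I_applied + Σ_j W_ji s_j(t)`,

with alpha-synapse kernels `s(t) = α² t e^{-αt}` integrated exactly as the
linear filter `z' = -αz` (+ `α²` at each presynaptic spike), `s' = z - αs`.
Euler integration at `dt = 0.01` per iteration; an absolute refractory
period `tau_ref` holds the membrane at rest after each spike, capping
single-neuron rates at `1/tau_ref`. Noise is a white-noise current: each
step adds `noise_amp * sqrt(dt) * N(0,1)` to the membrane. We interpret the
stated amplitude (1.5) in this Wiener scaling deliberately: interpreted as
a per-step current of SD 1.5, the stationary membrane SD is ~0.11, a
silenced pool sits tens of SDs below threshold, and the switch never flips
spontaneously — contradicting the described baseline behaviour in which
noise produces spontaneous and failed transitions. Under Wiener scaling the
stationary membrane SD is ~1, and the switch shows exactly that
phenomenology.

The network: 25 R-pool and 25 N-pool neurons, cross-pool inhibition with
connection probability 0.5 and weights uniform on [0, 1] divided by `d`
(N→R: d = 2.1, max 0.48; R→N: d = 2.5, max 0.4 — the asymmetric operating
point), no within-pool connections, bias currents 2.0 with the noise above,
and a 10-neuron input pool (bias 0) connecting with probability 1 and fixed
weight to the ramp target: excitatory onto R (`ramp_r`) or inhibitory onto
N (`ramp_n`). The REM drive is held at zero for 2000 iterations and then
rises by 0.06 per iteration. Outputs are pool-mean spike counts per
20-iteration epoch (400 epochs), smoothed over 3 epochs; the R-minus-N rate
difference is scored N / NRt / R by two thresholds with a two-epoch
persistence rule.

### Thresholds

The scoring thresholds are derived from pooled ramp-free baseline runs:
kernel-density mode detection (standard bandwidth, then halved twice,
because the minority REM mode is narrow), accepting a mode pair only when
both peaks stand at least 2× above the intervening trough, the minor peak
reaches 4 % of the maximum, and the modes are at least one SD apart;
`thr_N` and `thr_R` are the midpoints between the trough and each mode.
Unimodal pools are a hard error ("switch not bistable"). The
mode/trough-midpoint construction is ours — the method's source states that
thresholds were derived from baseline simulations without giving the rule.

### Free parameters and how they were fixed

The integration step, synapse speed, input weight, refractory period and
inactivation depth are not published; they are exposed as arguments with
defaults `dt = 0.01`, `alpha = 2`, `input_weight = 0.025`,
`tau_ref = 0.25`, `inhib_delta = -0.5`. The last three were calibrated once
against the published *qualitative* switching behaviour, which is the study
condition the simulations must reproduce:

* without a rate cap (`tau_ref = 0`) the linearly ramping drive grows
  without bound through the input pool's firing rate, and the post-
  transition REM state becomes noise-proof — no REM-origin NRt can occur in
  the ramp-to-R configuration, contrary to the described experiments; a
  0.25 refractory period caps the drive at a physiological scale;
* `input_weight = 0.025` places the deterministic switching threshold
  inside the simulated window while leaving the REM state marginally
  stable (larger weights lock it, much smaller ones fail to switch);
* `inhib_delta = -0.5` (a quarter of the operating bias) produces
  condition effects resolvable at 15-network replication; the spec-
  suggested −0.2 left them below the noise floor.

Because these are surrogates for unpublished values, every experiment test
asserts **signs and orderings only**, never magnitudes. Note one
consequence: at the experiment-grid defaults the noise-free switch cannot
flip (the capped drive cannot cross the inhibition gap without noise), so
the noise-free determinism property is exercised at `input_weight = 0.08`,
where the crossing is deterministic.

### Experiments

`run_experiments()` builds `n_networks` random connectivity matrices
(shared across scenarios and conditions), derives thresholds once from
ramp-free baselines, simulates baseline / R-inhibition / N-inhibition /
combined inhibition with shared noise seeds (paired design), drops networks
whose baseline run is REM-dominant from onset (first scored epoch R), and
reports per-run REM-origin and NREM-origin NRt densities (bouts per epoch
of the origin state) and latency to the first R epoch (censored at 400).
Condition effects are paired mean differences — counts per run are small
(0–2 bouts), for which means are the resolvable statistic.

## 3. Muscimol diffusion

One iteration = one minute = one application of the normalized size-3
Gaussian kernel (SD 1.2 voxels) to the whole 250³ field, followed by the
scheduled source reset at the central voxel: 307 mM for iterations 1–30
(microinjection; 20 µg over 30 min into the 19 nl probe-tip volume — the
dose arithmetic is `source_concentration_microinjection()`), or 0.085 mM
on every one of 150 iterations (microdialysis). Concentration maps to
percent spike inhibition through `PSI(c) = 4e-7c³ − 7e-4c² + 0.45c` (c in
nM); the inhibition radius is the interpolated distance along a principal
axis where PSI falls below 1 % (concentration ≈ 2.23 nM, the positive root
of the cubic; the rounded 2.5 nM literature anchor is available as an
option — the ratio of the two scenarios' radii is insensitive to the
choice). The voxel scale is calibrated by equating the microinjection
radius to the 2 mm suppression radius measured around comparable
microinjections.

Numerics: the production path never materialises the 250³ array. Because
the kernel is separable and the update linear, the field along an axis
through a central source is an exact superposition of 1-D kernel
self-convolutions, with each scheduled reset entering as an impulse
correction at the source; the test suite verifies this path against a dense
3-D implementation (replicate-edge padding) to machine precision on small
grids, along with kernel normalisation, mass conservation, axis symmetry,
radial monotonicity, and linear scaling in the source concentration.
Boundary handling is irrelevant at full scale: the source sits ≥124 voxels
from every face, more than 8 effective SDs at iteration 150.

One tension is worth recording. With SD fixed at 1.2 the microdialysis
concentration at the source-adjacent voxel settles near 17 % of the source
concentration, not the 20 % tissue-phantom anchor the SD was reportedly
tuned to. The plateau is monotone in SD only below ~1 (≈27 % at SD 0.4
falling through 20 % near SD 0.79), so both statements cannot hold at once
under this kernel convention. The package therefore treats SD 1.2 as the
default (it reproduces the published 61 % radius ratio) and provides
`calibrate_sd()`, which solves for the SD that hits a requested plateau —
the calibration procedure described for the original analysis. The
dose–response cubic holds a second recorded tension: `psi(10) = 4.43 %`,
although the effect is described as approaching zero near 10 nM; the
printed polynomial is implemented as printed.

## 4. The synthetic-recording generator

The generator emits at the state-space/band-power level — the analysis
consumes band powers, so fidelity is needed only there. Its defaults
describe a rat-like recording in 5-s epochs:

* three clusters: NREM at (−0.55, 3.0), REM at (−0.12, 2.2) (centres ~24
  pooled walk SDs apart; a 6-SD floor is enforced), wake at (−0.62, 2.55),
  off the NREM–REM axis on the side away from the corridor so that
  wake–sleep travel epochs cannot drag the cluster envelopes toward
  transitionary space;
* within-cluster AR(1) walks (φ = 0.5, innovation SD 0.04; the REM cluster
  walks faster and wider, φ = 0.3, SD 0.06 — REM EEG is the more labile
  state) plus independent per-epoch observation noise (SD 0.025) standing
  in for single-periodogram estimation variance; this noise is what makes
  trajectories self-intersect densely inside clusters, as real ones do;
* geometric dwells with physiological minimums (NREM mean 45 epochs,
  minimum 12 — NREM consolidates before a REM transition; REM mean 30;
  wake mean 18; brief arousals at hazard 1/200, 1–3 epochs);
* a transition corridor spanning the central half of the inter-cluster
  axis: complete transitions take 6–18 epochs with a lateral bow and
  per-traversal entry/exit offsets; failed excursions (hazard 1/500 per
  NREM epoch, 1/2000 per REM epoch — REM-origin failures are rare at
  baseline, matching their in-vivo scarcity) travel 38–60 % of the way and
  loop back on the opposite side of the axis, so the trajectory never
  retraces itself (directed transitionary dynamics is precisely the
  assumption the boundary method needs); corridor entry and exit are
  continuous with the cluster walk;
* a drug condition multiplying the REM-origin excursion hazard by 6, NRt
  durations by 2, and the sleep-to-wake propensity by 0.7.

Band-power inversion fixes the 1–19 Hz total from `y` and the 7–9/1–9
ratio from `x`; the remaining 13 degrees of freedom carry lognormal noise.
`generate_raw_eeg()` reverses the spectral module exactly by constructing
the DFT per epoch (band power split evenly over bins, random phases,
Hermitian symmetry).

What the generator does **not** emulate: EMG, artifacts, circadian
structure, REM homeostasis and rebound, and the mixed frequency content of
real wake. Passing closed-loop tests therefore shows that the scoring
pipeline recovers transitions whose geometry matches its assumptions — not
that it would perform identically on any real recording.

Calibration: the closed-loop requirement (epoch-level t sensitivity and
specificity ≥ 0.9 on a 4-h recording with 2-h control) was used to fix the
generator defaults once, by removing generator artefacts the in-vivo method
never faces — trajectory jumps at corridor entry, excursions retracing
their own path (whose turn-around points masquerade as within-cluster
intersections), unphysiologically short pre-transition NREM bouts — after
which the pinned calibration recording (seed 1) passes with margin. At
elevated excursion rates the cluster envelopes can be dragged into overlap,
which the pipeline reports as a hard error rather than scoring unreliable
boundaries.

## 5. Estimation statistics

Paired mean differences with 95 % BCa bootstrap intervals (5000 resamples
of pairs via the `boot` package, jackknife acceleration) and Cohen's *d*.
The paired *d* uses the SD of the pairwise differences; the variant is
recorded in every result. Zero-variance differences yield a degenerate,
flagged interval equal to the point estimate rather than an error or an
infinite statistic. Resampling is always of pairs, never of pooled values,
and the RNG seed is explicit.

## 6. Problem sizes used by the tests

The suite runs the scorer's closed loop on 2880-epoch recordings, the
experiment battery at 15 networks × 2 scenarios × 4 conditions, tuning
cells at 2–5 repetitions (the full 121-cell × 25-repetition design is
enumerated, not executed), dense-grid diffusion checks at 15–41 voxels per
edge (the profile path is exact at any size), and bootstrap coverage at
500 replicates × 5000 resamples. These sizes were chosen so the whole
suite completes in about a minute while every statistical check retains
resolving power.
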