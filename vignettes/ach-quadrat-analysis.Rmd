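---
title: "Quadrat-level analysis of striatal acetylcholine dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrat-level analysis of striatal acetylcholine dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achdyn)
```

## The measurement model

Two-photon movies of a genetically encoded acetylcholine (ACh) sensor in
the dorsal striatum report local ACh concentration through the fraction of
sensor bound. `achdyn` models the sensor as a bimolecular binding
reaction,

$$\frac{dB}{dt} = k_{on} A(t)\,(1 - B) - k_{off} B,$$

with the published iAChSnFR rates ($k_{on} = 0.62\ \mu M^{-1} s^{-1}$,
$k_{off} = 0.73\ s^{-1}$). The observed relaxation rate at concentration
$A$ is $k_{obs} = k_{on} A + k_{off}$, giving an activation time constant
of about 144 ms at 10 µM and a few ms at 1 mM — fast enough that the
timing of measured dips reflects ACh dynamics rather than sensor
filtering. `sensor_bound_fraction()` integrates this equation with the
exact per-frame update for piecewise-constant input (no numerical
integration error), starting at the equilibrium bound fraction for the
initial concentration.

The imaging signal of each quadrat (one cell of a 15 × 15 grid tiling the
field of view, ~50 × 50 µm) is summarized as

$$\frac{\Delta F}{F}(t) = \frac{F(t) - F_0}{F_0}, \qquad
z(t) = \frac{\Delta F/F(t) - \mu}{SD},$$

where $F_0$ is the mean fluorescence over a per-trial 2-s pre-tone
baseline and $\mu, SD$ come from the 1-s window immediately before the
trial outcome. Because ΔF/F cancels any static multiplicative structure
(vignetting, tissue texture) and z-scoring cancels gain, the pipeline is
invariant to affine rescaling of the raw signal — a property the test
suite asserts directly.

**Baseline choice.** The in-vivo baseline is computed *per trial* (the
2 s preceding the start tone), not per session. A session-wide baseline
would leak slow drift into ΔF/F; the per-trial choice makes each trial's
normalization local and is the convention used throughout. This is a
deliberate, documented decision — do not change it silently, as all
downstream amplitudes are calibrated to it.

## Stage by stage

### Registration

Rigid x–y motion is estimated per frame by maximizing the normalized
cross-correlation between a central crop of the template (the mean
projection by default) and the corresponding window of the frame, over
integer shifts within ±8 px (configurable). Cropping the template by the
search radius keeps the compared area constant, so the criterion is a true
correlation coefficient for every candidate shift; the numerator is
computed by FFT and the window norms by integral images, making the search
exact and fast. Sub-pixel refinement and non-rigid warping are out of
scope: the physical artifact being removed is spatially uniform
translation.

### Quadrat extraction

Frames are optionally denoised with a separable Gaussian (σ = 2 px in x,
y and t, reflective boundaries) and block-averaged into the grid. At the
default 150 × 150 px test geometry no cropping is needed; at 512 × 512 a
centred symmetric crop to divisibility is applied and reported. Quadrat
indices are 1-based and column-major; row 1 is the anterior edge before
any mirroring.

### Outcome alignment and quantification

Windows of ΔF/F from 1 s before to 1 s after each outcome (extensible to
[−5, +2] s) are z-scored per trial. Trials whose window leaves the
recording are dropped with a message; trials with zero baseline SD are
flagged, and scored against a caller-supplied nominal SD when one is given
(this is how noiseless synthetic data are processed: the generator's
ΔF/F-per-z calibration serves as the known noise floor). The
outcome-response quantifier reports the dip (minimum), peak (maximum),
their latencies (ties break to the earliest frame), and onset (first
|z| > 1 crossing) over the half-open [0, 1) s window. All windows in the
package are half-open, and one time step is one frame at 30 Hz.

### Clustering and the rule taxonomy

Trial-averaged quadrat traces are reduced by PCA to the smallest number of
components explaining 90% of variance, clustered by Euclidean
complete-linkage agglomeration, and the cluster count is chosen at the
maximum discrete second difference of the within-cluster sum of squares
(ties to the smallest k; k can also be pinned, e.g. at 4). Silhouette
coefficients (singletons scored 0) quantify separation — on real data
these are expected to be low (graded response continua), which is why the
rule-based taxonomy exists as a second, threshold-anchored labelling:

* **increase–decrease**: z > +2 for ≥1 frame in [0, 0.4) s, followed by a
  pause. "Followed by a pause" is not further specified in the source
  convention, so it is operationalized here as a minimum below −2
  occurring strictly after the early peak, within [0, 1) s.
* **decrease–increase**: minimum below −2 plus a rebound above +2 in
  [0.5, 1) s after the dip.
* **decrease**: never above +1 in [0, 1) s and minimum below −2.
* **increase**: above +2 without a qualifying decrease.

Traces satisfying several rules are resolved by the precedence order
above (the source convention is silent; fixing a precedence makes the
labelling deterministic). Anything else is `unclassified`. Note that a
quadrat matching the *population-mean* reward dip of −1.64 z does not
cross the −2 SD decrease threshold: with the default templates the pause
type is therefore reported `unclassified` — a faithful consequence of the
two published numbers, and harmless for recovery checks, which compare
partitions (adjusted Rand index) rather than label strings.

Responsiveness (positive / negative / non-selective) is a two-tailed
paired t-test (α = 0.05) of per-trial evoked means (0.3–1.3 s
post-outcome) against the 1-s baseline; the same window is used for
reward and no-reward outcomes for symmetry, although the source
convention states it only for the no-reward/switch–stay analysis.
Constant non-zero differences (possible on synthetic data) force the sign
through an ε-guard rather than dividing by zero. Ramps are classified by
the closed-form slope t-test of z on time over the last 5 s before the
outcome. Switch/stay groups combine two responsiveness calls — on
no-reward trials preceding a switch and preceding a stay — into nine
groups; "switch" means the *immediately next* choice differs (the
alternative "any upcoming trial" reading is not used). No
multiple-testing correction is applied across quadrats; classifications
report raw P values by design, and count summaries inherit that.

### Spatial mapping

Quadrat (row, col) maps to anatomical coordinates as
`offset = (index − 8) × 0.05 mm × scale`, mirrored per the lens flags and
added to the implant centre; cell 8 (the midpoint of an odd 15-grid) is
the anchor, so offsets span ±0.35 mm. Mediolateral values are mm from the
midline, anteroposterior values mm from bregma with anterior positive and
row 1 anterior. Grids 3–13 on both axes are "central" (121 quadrats),
the outer two rows/columns "peripheral" (104). Axis gradients are tested
by regressing per-bin type proportions on the bin coordinate (default one
bin per grid line); the F0 control correlates per-quadrat baseline
fluorescence with mean evoked z to detect vignetting leakage.

### Statistics

Unpaired comparisons use classical pooled-variance Student's t (not
Welch), matching the stated convention; χ² has no continuity correction;
Cohen's d uses the pooled SD with the normal-approximation CI
$SE = \sqrt{(n_1+n_2)/(n_1 n_2) + d^2 / (2(n_1+n_2))}$; printed
percentages round half-up to one decimal. The two-way repeated-measures
ANOVA requires a balanced complete design and refuses to impute.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
ground truth without any recordings. It emulates:

* **Movies** — 30 Hz, default 150 × 150 px (512 × 512 supported) tiled by
  the 15 × 15 grid; per-pixel intensity
  `vignette × texture × F0 × (1 + ΔF/F) × bleach + noise`. Vignetting is
  a radial attenuation (default 40% at the corner) emulating GRIN-lens
  edge fall-off; the static multiplicative texture stands in for tissue
  structure and is what anchors registration; bleaching defaults to zero
  in vivo (no bleach-correction step exists in the in-vivo pipeline —
  bleach correction belongs to the slice-puff analysis). Motion jitter is
  integer-pixel, with the schedule recorded as ground truth. A second,
  ACh-insensitive channel (static baseline + noise) emulates a
  co-expressed red fluorophore control and must show no outcome-locked
  response — asserted across 20 seeds.
* **Responses** — each quadrat carries one of four templates per outcome.
  Lobes are raised cosines: smooth, unimodal, with analytic extrema, the
  simplest shape satisfying the published (amplitude, onset, latency)
  triplets, which do not constrain the waveform between those landmarks.
  The reward pause is pinned at −1.64 z (onset 0.23 s, dip 0.48 s) and
  the no-reward pause at −0.89 z (onset 0.25 s, dip 0.65 s) — the
  published population means. The burst/rebound lobes of the other types
  are unconstrained by published values; they are set to ±2.2 z (so each
  type crosses the ±2 SD thresholds defining it) with near-disjoint lobe
  windows, making the four type means roughly equidistant in trace space.
  That geometry is a design choice for the recovery benchmark: the
  maximum-second-difference elbow resolves all k clusters only when the
  merge costs are comparable, i.e. when the types are about equally
  distinct. Real data, with graded morphologies and dominant clusters,
  will not satisfy this — which is exactly why passing the noiseless
  recovery test shows pipeline correctness, not that the elbow will find
  four clusters in any recording.
* **Behavior** — daily sessions of ~40 trials; P(correct) rises
  exponentially toward 0.95 during acquisition (rate 0.02/trial, reaching
  the 80% criterion in 3–5 sessions); the session after the criterion
  starts with 10 old-contingency trials and then reverses without a cue.
  Post-reversal choices follow win-stay (P = 0.95 after reward) and an
  ACh-coupled lose-shift: each unrewarded trial draws an ACh response
  amplitude (z units, N(2.5, 0.8)) and switches with probability
  `plogis(−2 + coupling × ACh)`; the chemogenetic-inhibition factor
  multiplies the coupling, so factors < 1 lower lose-shift at matched
  seeds. Trial latencies shorten from ~71 s to ~28 s across learning;
  licks are Poisson per 40-cm bin with the anticipatory surplus confined
  to the pre-outcome bin (280–320 cm) on expected-reward approaches;
  positions are constant-speed traversals of the 0–320 cm track. All
  randomness flows from a single integer seed.

What the generator does **not** emulate: photon shot noise (noise is
Gaussian), optics/PSF, neuropil contamination, non-rigid motion, reward
anticipatory ramping in the fluorescence (pre-outcome baselines are
flat), and within-session drift of behavioral strategy beyond the
stay/shift rule. Tests passing on this generator demonstrate algorithmic
correctness under the stated assumptions, not robustness to every
property of real recordings.

## Behavioral error taxonomy

Post-reversal trials are scanned in consecutive, non-overlapping blocks
of four (the "block of four trials" phrasing reads most naturally as
disjoint blocks). While blocks contain ≥3 incorrect trials, their errors
are perseverative; the sequence ends at the first block with ≥2 correct,
and from that block onward every error is regressive. Counting the
terminating block's own errors as regressive is the one reading
consistent with the worked example this implementation is validated
against; trailing trials that do not fill a block are ignored. Undefined
ratios (e.g. a lick index with zero licks on both arms, or lose-shift
with no qualifying transitions) propagate as `NA` with a flag — never
as 0.

## Numerical choices and problem sizes

* Closed-form updates wherever they exist: sensor binding (exact
  exponential update), ramp regression (analytic slope t-test), NCC
  (FFT + integral images).
* Bleach correction fits a natural cubic B-spline basis (df = 5 by
  default) restricted to the two response-free windows (0.5–4.5 s and
  14.5–19.5 s around a puff at 5 s), then subtracts the prediction over
  the whole trace; the masked-out response region is bridged by the
  spline's smoothness. The ΔF/F baseline is the 4.5 s before puff onset.
* Ties: earliest frame wins (dip/peak latency, elbow k).
* The test suite and acceptance checks run on deliberately compact
  problem sizes — 150 × 150 px movies of ~20–30 s, 11 simulated fields
  for cohort counts, 300 trials for parameter recovery, 10 000 replicates
  for type-I calibration, 20 seeds for stochastic properties — chosen so
  the whole suite completes in a few minutes while keeping Monte-Carlo
  error well inside the asserted tolerances.

## Known limitations

* The elbow criterion is a heuristic; on data without comparably distinct
  clusters it will under- or over-estimate k (pin `k` when an external
  count is justified).
* Registration is integer-pixel and rigid by design.
* The repeated-measures ANOVA handles only the balanced two-factor
  within-subject design used here; Tukey post-hoc contrasts beyond that
  design are out of scope.
* The generator's behavioral model is a two-parameter stay/shift process;
  it reproduces the directionality and coupling structure of
  reversal-learning behavior, not its full richness (no
  session-to-session consolidation, no side bias).
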