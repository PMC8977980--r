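---
title: "Driver mapping from multi-electrode electrograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver mapping from multi-electrode electrograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

afdm implements a complete analysis chain for characterizing atrial
fibrillation (AF) drivers recorded with a five-spline, twenty-electrode
mapping catheter, together with the outcome statistics that link driver
location to post-ablation recurrence. This vignette documents the models,
the tunable parameters, the synthetic-data generator used for validation,
and the numerical choices that an analyst or reviewer would want stated
explicitly.

## Signal model and activation annotation

A unipolar electrogram is annotated at its **local activation time (LAT)**,
defined as the instant of maximum negative slope of the signal — the
standard unipolar landmark, which coincides with the passage of the
depolarization wavefront under the electrode. `detect_lats()` smooths the
channel with a short moving average (default 5 samples at the 1 kHz default
sampling rate), estimates the derivative by central differences, and keeps
local derivative minima below an adaptive threshold, greedily by slope
magnitude under a refractory constraint:

* `refractory_ms` (default 60 ms) — a sub-physiological floor for the atrial
  refractory period; two annotations on one electrode can never be closer.
* `slope_floor_mv_per_ms` (default adaptive) — six times a robust estimate
  of the derivative noise SD (scaled MAD, with a quietest-decile fallback).
  The factor six keeps the expected number of noise-only threshold
  crossings over a full 30-s, 20-channel acquisition far below one, while
  physiological downstrokes exceed the floor by an order of magnitude. A
  smoothing window much shorter than the ~10 ms deflection is essential:
  averaging across the whole biphasic deflection cancels it.

The **dominant cycle length (DCL)** is the median over electrodes of the
per-electrode median inter-activation interval (`dominant_cycle_length()`),
with electrodes carrying fewer than three activations excluded. The
median-of-medians was chosen over a spectral dominant frequency because it
is robust on short windows and insensitive to occasional missed or double
annotations; the method tag is recorded in the result for auditability.
Values outside 100–300 ms warn, reflecting the plausible fibrillatory band.

## Rotational activity (RAc)

A rotor anchored near the catheter center activates the five electrodes of
each concentric ring sequentially, so the ring's LATs trace a "staircase"
spanning most of one cycle; with five equally spaced electrodes a full
rotation spans exactly 4/5 of the cycle length. `detect_rac()` slides
beat-by-beat (beats anchored on the external-ring electrode with the most
annotations) and, per ring, takes for each electrode the LAT nearest the
window center. A rotation qualifies when at least `rings_required` rings
are simultaneously staircase-ordered with identical chirality and a span
fraction above `span_threshold` (default 0.5 — more than half the DCL).
Runs of at least `min_rotations` (default 2) consecutive qualifying
rotations with constant chirality become events.

Design points worth stating:

* The span rule is applied **per ring**, with `rings_required = 4` as the
  strict default; the requirement can be relaxed for sensitivity analyses.
* A staircase is a strictly monotone circular sequence modulo one
  wrap-around step (exactly one sign reversal among the five circular
  increments). The wrap tolerance matters because the beat-window
  assignment can legitimately rotate one electrode's annotation into the
  neighboring cycle; span and chirality are unaffected.
* Chirality must be constant across rings and rotations within one event;
  a reversal splits the event, since a rotor has a single handedness.
* `confirm_rac()` is an automated surrogate of expert review: confirmed iff
  the event has more than 2 rotations **and** the electrical-burden score
  on at least one internal-ring bipole is higher inside the event than
  outside by `margin` (default 0.15), emulating "appearance of continuous
  activity" at the core. Both raw and confirmed event sets are retained so
  the surrogate never silently discards data.

## Focal activity (FAc)

A focal source produces a **QS pattern** — a monophasic negative unipolar
deflection — at its origin, because tissue at the source sees only a
departing wavefront. `classify_qs()` quantifies this as the ratio of
maximum positive to maximum negative excursion inside a 40-ms window
centered on the LAT; the deflection is QS when the ratio is strictly below
0.15 and the negative excursion clears the channel noise floor. The 0.15
cut quantifies "no significant R wave"; the morphology rule itself names no
number, so the ratio is exposed as a parameter.

`detect_fac()` applies the earliest-origin rule: a QS activation is an
origin candidate iff no other QS activation within a 10-mm radius has its
LAT in the 50 ms before it. Candidates on consecutive beats (beat grid from
the DCL; a missed intermediate beat breaks the chain — the strict reading
of "consecutive") with per-beat origin drift up to the same 10-mm radius
form events of at least `min_beats = 2` beats. Co-located simultaneous
candidates within one beat are reduced to the earliest (ties to the lowest
electrode index), so a source equidistant from several electrodes yields
one event rather than several parallel ones.

## Electrical burden (two-state HMM)

The burden of a bipolar channel is the fraction of time it shows electrical
activity, scored in [0, 1]. `extract_activity_features()` computes
log(1e-12 + mean squared amplitude) over 50-ms frames hopped by 25 ms —
at fibrillatory cycle lengths (~170 ms) this resolves activity with at
least three frames per cycle. `fit_burden_hmm()` fits a fully unsupervised
two-state Gaussian hidden Markov model by EM (Baum–Welch with scaling),
k-means-initialized with 5 restarts, picks the restart with the best
log-likelihood, decodes with Viterbi, and reports the active-frame
fraction; the state with the larger emission mean is "active". Identical
seeds give identical results; degenerate zero-variance states are floored
at 1e-6 of the feature variance and flagged.

Because the features are log energies, a global amplitude rescaling only
shifts both state means, so the score is amplitude-invariant. That
invariance makes a *single-regime* channel (all silence or all activity)
undecidable from the frame energies alone: when the two fitted means are
separated by less than 6 dB (`min_separation = log 4`), the channel's
regime is decided by its low-band power fraction — the variance retained
under a 5-sample moving average, which is ~1/5 for broadband noise and
>0.5 for band-limited physiological deflections, thresholded at the
midpoint 0.37. A channel dominated by narrow-band interference rather than
white noise would defeat this fallback; the two-regime path, which handles
every mixed channel, does not rely on it.

## Mesh merging and regional analysis

Patient shells are merged onto a reference left atrium in two stages
(`center_mesh()`, `nonrigid_icp()`): exact centering of the vertex centroid
at the origin, then registration. Because an atrial shell is nearly
spherical, closest-point correspondences observe rotation poorly, so the
rigid stage fits the pose to paired anatomical landmarks (PV ostium
centroids, appendage apex, mitral-rim centroid) before iterative
closest-point refinement, and keeps the identity pose unless the
landmark-initialized one fits the surface clearly better (a pure
deformation can masquerade as a rotation). The non-rigid stage solves, at
each level of a decreasing stiffness schedule (default 50, 20, 8, 3, 1,
0.3), the Laplacian-regularized system `(W + lambda L'L) D = W (C - X)`
for the per-vertex displacement `D`, where `C` are symmetric closest-point
targets (forward nearest neighbor averaged with the reverse-assigned
reference vertices — the symmetric form suppresses tangential sliding) and
`W` up-weights eight anatomical anchor points (appendage apex and the
seven region seeds) that carry the tangential information a near-spherical
surface otherwise hides. This concretizes "non-rigid ICP" as a
displacement-smoothness-regularized variant; the schedule is exposed.

Scalars and driver sites are carried through the registration
(`map_points()`) and projected to nearest reference vertices
(`project_scalars()`), averaging collisions, dropping points farther than
`max_distance_mm` (counted), and flagging untouched vertices unobserved.

`segment_regions()` produces the nine-region partition: appendage = the
surface enclosed by the neck loop; PV antra = vein surfaces enclosed by the
ostium loops plus the 1-cm geodesic band around them, with the
left-superior antrum truncated at the appendage ridge (vertices
geodesically closer to the neck than to the ostium stay on the appendage
side); all remaining vertices by geodesic Voronoi from the seven wall/
mitral seed landmarks. Geodesic distances are shortest paths on the
triangulation edge graph augmented with 2-ring chords (igraph), which
reduces the metric anisotropy of the graph approximation to a few percent;
the "1 cm" antra rule is interpreted geodesically because it lives on the
surface. Landmarks are explicit inputs, so a human can dictate them
exactly as in a manual workflow.

`classify_driver_location()` is a geodesic point-in-region test: removing
the closed ablation-line loops disconnects the encircled antral surface;
a site maps to its nearest vertex and is "inside" iff that vertex is on
the line (boundary sites are presumed ablated) or in a component holding
PV ostium vertices. `voltage_metrics()` weights each vertex by one third
of its incident triangle area and reports the mean and the strictly-below
area fractions at 0.5, 0.35 and 0.1 mV — the conventional thresholds for
low-voltage/scar surrogates.

## The synthetic-data generator

All validation runs on synthetic data with known ground truth; no clinical
recordings ship with the package.

* **Catheter** (`make_catheter_geometry()`): four concentric rings of five
  electrodes (radii 10/7/4/2 mm by default — nominal values, the clinical
  spacing is not standardized in exports), five splines 72 degrees apart,
  bipoles along each spline. A `deployment` parameter domes the inner
  rings out of plane purely to create rejectable fixtures; analyses assume
  a deployed, in-contact catheter.
* **Activation fields** (`simulate_activation_field()`): planar, focal and
  rotational phase models with per-beat i.i.d. Gaussian jitter and a
  refractory floor. Fibrillatory irregularity is *only* this jitter plus
  amplitude scatter; there are no restitution dynamics, wavebreaks, or
  meander, so detector sensitivity on these fields is an upper bound for
  real recordings.
* **Electrograms** (`synthesize_unipolar()`): biphasic deflections are
  derivative-of-Gaussian (RS) and focal origins monophasic negative
  Gaussian (QS), both 10 ms wide by default and inserted so the maximum
  negative slope lands exactly on the generated LAT (the QS template is
  shifted by one sigma for this purpose — only the slope landmark and the
  morphology matter to the detectors). White noise, default 0.02 mV SD
  against 1 mV deflections; bipoles are channel differences.
* **Burst channels** (`simulate_burst_channel()`): alternating
  active/silent segments with exponential lengths of means
  `duty * 2000 ms` and `(1 - duty) * 2000 ms`, so the long-run active
  fraction equals the duty cycle while both dwell times remain resolvable
  at the 50-ms frame across the whole sweep; the realized per-sample
  activity mask is returned as the scoring oracle.
* **Atrium** (`make_synthetic_atrium()`): a 33-mm spherical shell (cavity
  ~150 cm^3, typical of a persistent-AF atrium) with four PV stubs
  emerging laterally (so a posterior wall remains between the antral
  pairs), an appendage protrusion, 0.15-mm surface roughness, planted
  ground-truth region labels constructed in the same frame, fibrosis
  patches overriding a base voltage, and a closed ablation line around
  each PV pair. The spherical default makes the planted angular
  construction an exact continuum-geodesic truth, so segmentation accuracy
  against it measures only the algorithm and the graph discretization.
  Label agreement at the default 900 vertices is ~91% and >= 95% at 1800
  vertices (the boundary band shrinks with edge length); the segmentation
  agreement tests therefore use 1800-vertex shells.
* **Cohorts** (`simulate_cohort()`): 64 men and 21 women by default, with
  gender-specific RAc prevalence (73.4% / 38.1%), voltage, and confounder
  distributions (women older, more hypertensive, higher CHA2DS2-VASc,
  smaller BSA), an 82% probability that an RAc patient harbors a site
  outside the ablation line, and recurrence drawn from a logistic model
  whose default carries an odds ratio of 4 for RAc-outside (about a
  baseline of 31% at reference covariates: 67% low-voltage area and
  148 cm^3 LA volume). About 7% of patients get follow-up inside the 90-day
  blanking window to exercise the exclusion rule.

## Cohort statistics

Contingency tables use Pearson's chi-square without continuity correction
(the convention that reproduces the printed gender-prevalence p-value of
0.003), switching to Fisher's exact test when a 2x2 expected cell is below
5 (`contingency_test()`); continuous comparisons use Welch's t-test and
proportions a pooled two-sample z-test. Odds ratios come from
maximum-likelihood logistic fits with Wald 95% CIs (the source analyses do
not state a CI method; Wald is the default and transparent choice), with
the multivariate adjustment set LA volume, LA area and scar (<0.5 mV)
fraction. Complete separation is detected and reported; a flagged
ridge-penalized fallback returns a point estimate without a CI. Firth's
bias-reduced logistic regression (`method = "firth"`) is available and is
what the odds-ratio recovery experiment uses: at the 85-patient study size
the plain maximum-likelihood Wald interval is measurably anticonservative
(~93% empirical coverage of the generating odds ratio over hundreds of
simulated cohorts), while the bias-reduced fit sits at its nominal 95%;
on a single binary exposure the Firth estimate reduces to the familiar
0.5-corrected cross-product ratio.

`propensity_match()` fits a logistic propensity model and matches 1:1 by
greedy nearest neighbor on the logit without replacement within a caliper
(default 0.2 SD of the logit), reporting standardized mean differences
before and after and never silently dropping unmatched treated subjects.
The balance experiment (`matching_balance_experiment()`) uses
`confounded_cohort_spec()` — strong (SMD 0.4–0.8) but overlapping
confounding — with a tight 0.05 caliper: under the default cohort's
near-separable BSA contrast there is essentially no common support, which
no matching algorithm can repair; that is a property of the population,
not of the estimator. Display percentages round half away from zero to
one decimal, matching printed-table conventions, while full precision is
kept internally.

## Problem sizes and reproducibility

The validation experiments (exported as `rac_detector_performance()`,
`fac_origin_recovery()`, `burden_duty_sweep()`,
`registration_experiment()`, `or_recovery_experiment()`,
`matching_balance_experiment()`) use 200 acquisitions per detector class
with ~10-beat windows, 9 duty levels x 20 seeded 10-s channels, 20 warp
fixtures on 900-vertex shells with smooth displacement fields (wavelengths
comparable to the shell, peak <= 5 mm), and 100 cohort draws at the study
size of 85 patients. Every stochastic component takes an explicit integer
seed, derives its sub-seeds from it, and restores the caller's RNG state,
so all results are bit-reproducible.

## Known limitations

* The activation model has no meander, wavebreak or collision; rotors are
  anchored at a fixed core for each event.
* Detector performance on synthetic fields bounds, but does not estimate,
  performance on clinical electrograms (no fractionation, far-field or
  motion artifact is simulated).
* The single-regime burden fallback assumes broadband baseline noise.
* Non-rigid registration assumes roughly comparable shell topology and
  available landmarks; displacement fields with spatial wavelengths near
  the inter-landmark spacing can still register imperfectly (the
  registration experiment reports the worst post/pre ratio for this
  reason).
* Recurrence is analyzed as a binary outcome after a blanking period;
  time-to-event modeling is out of scope.
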