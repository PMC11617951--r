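---
title: "Decoding tethered flight-mill recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding tethered flight-mill recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hovermill)
```

## The measurement model

A tethered insect flies in circles on a flight-mill arm of radius 0.09 m. A
sectored coding wheel and a dual-channel photointerrupter emit one
timestamped, directed transition per sector edge — 16 per rotation — so each
transition represents

$$d = \frac{2\pi r}{N} = \frac{2\pi \times 0.09}{16} = 0.0353\ \mathrm{m}$$

of arc. All conversions in this package use the exact value
`r format(distance_per_transition(mill_geometry()), digits = 6)` m rather
than the display-rounded 0.035: the exact value is what makes 72 transitions
in one second equal 2.54 m/s, whereas the rounded constant would give
2.52 m/s. Speed over an interval is $d/\Delta t$ between consecutive
same-sense transitions; anything downstream (distance, acceleration,
transect speeds) is built from this single constant.

## Error-correction passes

Raw streams carry two kinds of hardware error, each handled by a dedicated,
conservative pass that logs every change it makes.

**Direction glitches.** The sensor occasionally reports a spurious reversal.
A run of at most `max_reversal_run` (default 2) opposite-sense transitions,
flanked on both sides by runs of at least two consistent-sense transitions,
is reclassified when its observed time span is shorter than the minimum
physical duration of a true reversal at the local speed $v$:

$$T_{\min} = \frac{2v}{a_{rev}} + 2\sqrt{\frac{2nd}{a_{rev}}},$$

braking to a stop and re-accelerating plus traversing the run's $n$ sectors
out and back. The reversal acceleration `reversal_accel` defaults to
2 m/s², deliberately much smaller than the glitch bound
`max_biological_accel` (20 m/s²): an insect can produce brief thrust spikes
far exceeding what it can sustain through a full brake–reverse–resume
manoeuvre of a loaded arm, and a bound of 20 m/s² would make single-sample
reversals "physically possible" at cruising speeds below about 0.45 m/s,
leaving glitches at typical late-trial speeds uncorrectable. Slow sustained
alternation — the arm rocking as a non-flying insect shifts its weight — has
long spans and single-transition flanks, so it is never touched.

**Timing glitches.** A mistimed timestamp makes one interval too short and a
neighbour too long, implying a pair of adjacent accelerations outside any
biological range. Wherever two consecutive finite-difference insect
accelerations both exceed `max_biological_accel` in magnitude, both
endpoints of the offending interval are re-placed by linear interpolation
between the nearest trusted timestamps (which of the two timestamps is the
culprit depends on the glitch's sign, and interpolating both restores the
even spacing exactly when the surrounding speed is locally constant). The
pass repeats until clean, is idempotent on clean streams, and never changes
the number of events.

## Kinematics

Per transition the package reports speed; *residual speed*, the deviation of
speed from a trailing rolling mean over `residual_window` = 16 transitions —
exactly one wheel rotation, so sector-width asymmetry is detrended causally;
*observed acceleration*, a two-point finite difference of speed (higher-order
schemes would be false precision at this sampling); and *insect
acceleration*,

$$a_{insect} = a_{observed} + \mathrm{decel}(v), \qquad
  \mathrm{decel}(v) = c_0 + c_1 v,$$

where $\mathrm{decel}(v)$ is the arm's no-load deceleration from bearing
friction ($c_0$, speed-independent) and air drag ($c_1 v$). Adding it back
means a coasting arm reads as zero insect thrust, while steady flight reads
as the thrust needed to balance drag. The two-term form is the simplest model
that fits both regimes of a spin-down trial; `estimate_no_load_decel()` fits
it by least squares of $-dv/dt$ against $v$ from a free spin-down log and
recovers simulated arms within 10%. The defaults ($c_0 = 0.05$ m/s²,
$c_1 = 0.5$ /s) are the synthetic arm's truth; real hardware should be
calibrated from its own spin-down recording.

## Flight designation and segmentation

Forward movement is flight when speed $\ge$ 0.20 m/s, or $\ge$ 0.10 m/s
while insect acceleration $\ge$ 0.10 m/s² (a take-off that has not yet
reached cruising speed). Backward transitions never qualify. Qualifying
transitions are grouped into events, bridging internal non-qualifying gaps
up to `max_gap` = 1 s, and events shorter than `min_flight_duration` = 1 s
are discarded as movement too short to be a flight. The two 1-s defaults are
this package's own choices, config-exposed and logged; they sit an order of
magnitude above the inter-transition interval at threshold speed and an
order of magnitude below any behaviourally meaningful pause.

Because the coasting arm stays above 0.20 m/s for a second or two after
thrust ends, the detected flight end trails the behavioural thrust-off by
the coast-to-threshold time; once below 0.20 m/s the drag-corrected insect
acceleration is near zero, so the acceleration clause does not keep the
coast alive. Ground truth in the simulator records both the thrust-off time
and this crossing, and the round-trip tests hold detected ends within 2 s of
thrust-off.

Flights initiated in the final `crop_window` = 600 s are flagged: their
durations are censored by the trial end, so per-flight distributional
analyses exclude them, while whole-trial per-fly totals (distance, flight
time, initiation statistic) keep all events — matching how the published
per-flight and per-fly analyses differ in their event counts.

## Per-fly metrics

Per-flight aggregates weight time-dependent quantities by time (a plain
average over transitions would weight by distance); per-fly mean speed is
likewise flight-time-weighted, covering flight-designated data only — idle
time would otherwise dominate and drag wall-clock averages far below the
published per-fly speeds (0.28–1.88 m/s). The flight-initiation statistic is

$$\frac{14400 - \mathrm{FlightTime}}{N_{flights}}\ \mathrm{seconds},$$

mean idle seconds per initiated flight: a restlessness measure that does not
penalise flies that fly long uninterrupted bouts. It is undefined (NA, never
zero) for flies that never flew.

The time transect samples the half-open last second $[60m-1, 60m)$ of every
minute $m$: transitions inside designated flights are counted, `flying` is
their presence, and speed is count × $d$ — quantised to multiples of
0.0353 m/s by construction. Normalised time is $m/240 \in (0,1]$, so its
log is finite at the first sample; the published models' `time_log` term is
evaluated on the same grid.

## The published models

The fixture `inst/extdata/models.yaml` stores the printed coefficient sets
(with standard errors, links and dispersions) for whole-trial distance,
mean speed, flight initiation, per-flight distance, transect speed and
activity. Conventions:

* **Ordinal factors** (condition thin<medium<fat; size
  small<moderate<large) enter through orthonormal polynomial contrasts,
  linear $(-1/\sqrt2, 0, +1/\sqrt2)$ and quadratic
  $(+1/\sqrt6, -2/\sqrt6, +1/\sqrt6)$. The publication does not print its
  contrast weights; this convention is adopted because it reproduces the
  published prediction tables exactly within coefficient rounding (e.g.
  $\exp(6.00 - 1.08/\sqrt2 - 0.22/\sqrt6) = 171.9 \approx 171.8$ m), and the
  fixture records the convention used. It also gives the clean identity
  fat:thin $= \exp(\sqrt2\,\beta_{lin})$ — the quadratic term cancels.
* **Baselines**: morph = summer, direction = anti-clockwise.
* **Links**: log for the Gamma models; the flight-initiation model is a
  Gaussian linear model on log response, back-transformed with exp like the
  published table; activity uses logit.
* **Mixed models**: the per-flight, transect-speed and activity equations
  were published from mixed models. Their fixed-effect parts are evaluated
  as printed linear predictors; random-effect machinery is deliberately not
  implemented, since every published prediction target needs only the fixed
  part.
* **Prediction SEs** are propagated from printed coefficient SEs assuming
  independence — coefficient covariances are unpublished — so they are
  approximate and labelled as such.
* The dry-mass block is an additive condition + size model (the publication
  reports no interaction); `prediction_tables()` refits that additive
  structure to the printed cells at run time, so the medium/small prediction
  (7.48 mg) reproduces the printed 7.5 mg to its printed precision rather
  than being copied from it.

`fit_gamma_glm_log()` implements the Gamma/log GLM by IRLS for parameter
recovery studies. With a log link the working weights are constant, so each
step is a least-squares solve on the working response
$\eta + (y-\mu)/\mu$; iteration stops when the relative deviance change
falls below $10^{-10}$ (at most 100 iterations, an error on
non-convergence or rank deficiency). Dispersion is the Pearson moment
estimator; the printed 2.29 is fixture metadata, not a fitting target. The
tests cross-check coefficients, deviances and dispersion against an
independent reference GLM implementation to $10^{-6}$ and verify the
rescaling equivariance $y \mapsto cy$ shifts only the intercept by
$\log c$. Pseudo-$R^2$ is $1 - D_{res}/D_{null}$, with the null fitted mean
equal to the sample mean (the closed form for an intercept-only log-link
Gamma model).

## The synthetic cohort

The simulator exists so that every pipeline stage is testable with ground
truth and without the deposited recordings. Its defaults are the study
conditions: 141 flies in the published direction × morph × condition design
(sizes following the speed table's direction margins), population flight
occupancy decaying exponentially from 78% in the first minute to 8% in the
last, commanded bout speeds declining from an 0.84 m/s early median to a
0.35 m/s level after mid-trial, per-fly heterogeneity via a Gamma
multiplier with dispersion 2.29, and the published group-mean distances as
per-fly targets.

Mechanics and choices:

* **Bout schedule**: initiations are an inhomogeneous Bernoulli-per-second
  process realised through exponential waiting times with hazard
  $p(t) / (D (1-p(t)))$, where $D$ is the fly's mean (exponential) bout
  duration — the alternating-renewal identity that makes stationary
  occupancy track $p(t)$. Flies can already be airborne at $t=0$ with
  probability $p(0)$. $D$ varies between flies (log-normal, median 180 s),
  giving bout counts spanning the published 1–216 range.
* **Bout profile**: trapezoidal — ramp at 2 m/s², plateau, thrust-off,
  drag coast — the simplest profile that exercises the acceleration clause
  of the flight rule. Rendering uses closed forms (and Newton inversion of
  the concave coast arc-length under exponential drag) rather than
  small-step integration, so noiseless streams are exact to machine
  precision.
* **Distance calibration**: speeds, not durations, absorb the per-fly
  distance target (group mean × Gamma multiplier), clamped to
  0.25–2.0 m/s. Occupancy is the primary calibrated quantity; a fly whose
  target is unreachable within the speed bounds saturates rather than
  stopping flying. Group-mean distances are therefore reproduced only
  within those bounds (thin-condition groups saturate low), which is a
  deliberate limitation: the activity decay is the quantity the pipeline
  tests depend on, and scaling durations would distort it.
* **Noise**: direction glitches (probability $10^{-4}$ per transition),
  rocking episodes during idle gaps (alternating sense at ~0.05 m/s, six
  per idle hour), Gaussian timestamp jitter (0.2 ms) and 1 ms polling
  quantisation. All injected artifacts are catalogued in the ground truth
  so repair rates are measurable exactly.
* **Determinism**: each fly draws from its own seed substream keyed off the
  cohort seed, so cohorts are byte-reproducible and extensible without
  perturbing existing flies.

What the simulator does **not** emulate: within-bout speed wander,
wing-beat-scale torque, behavioural pauses shorter than a second,
temperature or lighting effects, and the full between-fly distance spread of
real cohorts (see the clamp above). Passing round-trip tests therefore
demonstrate the decoder's correctness on bout-structured, drag-coupled,
glitch-contaminated streams — not that real hoverfly data are this clean.

## Problem sizes and test tolerances

The test suite runs the full pipeline at the study scale (141 flies, 4-h
trials, ~7M transitions) once noiseless and once with default noise, plus
200 IRLS recovery replicates at n = 141; smaller cohorts (2–8 flies) back
the per-module tests. Tolerances: noiseless round-trips within one
transition of distance and 2 s of flight time per bout; ≥95% flight-second
recall with ≤5% false flight seconds; ≥90% glitch repair with ≤0.1% clean
alterations; activity endpoints within 3 binomial standard errors at
n = 141; published table cells within 2% (1% for the initiation cells),
which is the printed coefficients' rounding radius.

## Known limitations

* The event-log column layout of the original deposited data is not
  described in the publication; the CSV dialect here
  (`fly_id,t_s,sense`, forward = assigned rotation direction) is this
  package's own.
* The original study's exact pass-2 acceleration bound and its no-load
  deceleration measurement are unpublished; both are config-exposed
  parameters here.
* Prediction standard errors ignore unpublished coefficient covariances.
* The published flight counts (3,735 total; 3,607 modelled; 4,491 in the
  cropping note) imply filtering steps whose exact relationships are not
  specified; this package exposes the crop flag and per-fly totals so any
  of those filters can be reproduced explicitly.
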