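---
title: "Methods: rule-based ethograms, dF/F normalization, and defeat scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based ethograms, dF/F normalization, and defeat scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagematch)
```

`cagematch` analyses social-competition experiments that combine pose
tracking with fiber photometry.  This vignette explains the models and
procedures the package implements, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical and design choices a maintainer
would want written down.

## 1. The tube-test ethogram

Two mice meet head-to-head in a 30-cm tube; the mouse that forces its
partner to back out wins.  The classifier takes the nose and tailbase
x-coordinates of each mouse (the y-coordinate is kept only for QC), in a
calibrated tube frame, and evaluates per-frame predicates on smoothed,
signed velocities.  Each mouse carries a `facing` sign so that velocity is
always "toward the partner": +v means advancing, −v means giving ground,
for either mouse, which keeps every rule symmetric.

Positions are smoothed with a centred moving average (`smooth_frames = 5`
at 30 fps, i.e. a 1/6-s window — wide enough to suppress keypoint jitter,
narrow enough that a 0.2-s event survives) and differentiated by central
differences.  Low-confidence keypoints (likelihood < 0.6) are linearly
interpolated; a contiguous low-confidence gap longer than 1 s invalidates
the bout, which is skipped with a reason code rather than guessed at.

The predicates, for mouse *m* with partner *p*:

* **retreat(m)** — tailbase velocity ≤ `v_retreat_cm_s` (−2 cm/s) over an
  epoch whose cumulative backward displacement is ≥ `d_min_retreat_cm`
  (2 cm).  The displacement criterion separates true retreats from brief
  recoils.
* **body push(m)** — nose *and* tailbase velocity ≥ `v_push_cm_s`
  (+2 cm/s), noses within `nose_overlap_cm` (1 cm), and *p* not currently
  in a retreat epoch: driving into a partner who is already leaving is
  locomotion, not pushing.
* **nose push(m)** — as body push without the tailbase criterion: the
  head drives forward while the body stays planted, a lower-effort push.
* **resist(m)** — *p* satisfies a push predicate while *m*'s net tailbase
  displacement over that push stays below `d_min_retreat_cm`.  The
  behavior catalogue names resist without defining it kinematically; this
  hold-your-ground reading is our interpretation, and it is deliberately
  derived from the partner's push events so that every resist is paired
  with the push it answers.

Contiguous predicate-true frames form epochs; epochs separated by less
than `merge_gap_s` (0.3 s) merge; epochs shorter than `min_event_s`
(0.2 s) are dropped.  The numeric thresholds are conventions, not
published values — the original scoring describes only "a specified
threshold" — so all of them live in `ethogram_config()` and should be
re-tuned when a rig's optics or frame rate differ.  The staged order
(retreat epochs first, then pushes against the partner's retreat mask,
then resists from the final push events) is part of the definition: the
test suite checks the vectorized implementation against a brute-force
frame-by-frame oracle that follows the same order.

Rates are event initiations per second of bout, which normalizes for the
large variation in bout length.  A win is called when a mouse's tailbase
leaves the tube span on its own entry side by more than `win_margin_cm`
(1 cm) while the partner's tailbase is still inside; tailbase exit stands
in for "both rear paws on the ground outside the tube" because rear paws
are not tracked keypoints.  Cages are ranked per day by win count over the
round robin; a two-way tie breaks by the head-to-head bout, anything wider
is flagged and shares a rank.  A hierarchy counts as stable from the first
day of four consecutive identical rank vectors.

## 2. Photometry normalization and event-locked analysis

Two ΔF/F transforms are provided, matching the two recording
configurations.

**Isosbestic regression** (cell-body recordings with a 405-nm control):
the control channel is fit to the signal channel by ordinary least squares
(affine: slope and intercept over the whole recording — the source method
says only "least-squares", and the intercept costs nothing while absorbing
offset differences between channels), and
`ΔF/F = (signal − fit)/fit`.  Anything shared by the two channels —
photobleaching, motion artifact — cancels; calcium transients, present
only in the 470-nm channel, remain.  Two caveats are worth knowing: the
fit's intercept also absorbs the *mean* of the transient signal, so very
short recordings dominated by a single transient under-recover its mass;
and when the control channel's variance is dominated by a smooth bleach
trend rather than the artifact, transient mass can leak into the slope.
Both effects shrink with recording length and are negligible at the
session lengths the package targets (minutes).

**Sliding median** (single-channel terminal recordings): each sample's
baseline is the median of the signal in a 10-s window centred on it
(truncated at the recording edges — truncation, not reflection, so the
first and last 5 s use what data exist), and
`ΔF/F = (F − median)/median`.  The median is robust as long as transients
occupy less than half of any window; with GCaMP6s-like decay (~1.5 s) and
events a few seconds apart the local median sits a little above the true
baseline, which biases recovered amplitudes downward by roughly 10% — the
acceptance checks budget for this, and it is one reason the isosbestic
route is preferred whenever a control channel exists.

**QC.** Recordings whose P95 − P5 ΔF/F spread is below 1% (0.01
fractional) are excluded as lacking signal variation (poor expression or
fiber placement).  Percentiles use the linear-interpolation convention
(`stats::quantile` type 7); the convention is fixed and documented because
the verdict sits on a hard threshold.  ΔF/F is fractional everywhere
internally; "1%" means 0.01.

**Event-locking.**  Tube mode uses baseline [−1, 0] s, trace [−1, +5] s,
and includes only events from bouts strictly longer than 15 s (signal
around tube placement is contaminated by handling).  The strictness at
exactly 15 s follows the wording "longer than".  OFSI mode uses baseline
[−1.5, −1] s, trace [−1.5, +5] s, and excludes events preceded by another
event within 3 s (a gap of exactly 3 s is excluded), because the sensor's
slow decay would contaminate the baseline; the prior event counts even if
it was itself excluded.  Windows are aligned to the nearest sample — at
30–100 Hz that is at worst half a sample of misalignment, so no resampling
is done.  Each included segment is shifted by its baseline-window mean
(re-shifting is a no-op, which the tests assert) and quantified as the
mean over [0, 4] s; the optional 15-Hz zero-phase Butterworth replica of
the acquisition filter is available but not applied by default, since
simulated and demodulated signals arrive already band-limited.

## 3. Defeat outcome scoring

The open-field social-interaction test has two 150-s trials (empty chamber,
then a caged CD1 partner).  Occupancy is point-in-rectangle on the
centroid with closed boundaries; an entry is an outside-to-inside
transition, with a trajectory that starts inside counting as an entry at
its first frame.  The arena geometry defaults to a 44 × 44 cm box, the
10 × 6.5 cm chamber footprint centred at the far wall, the 24 × 14 cm
interaction zone centred on the chamber, and 9 × 9 cm corner zones at the
opposite wall; the corner geometry is not published, so it is a
config-exposed default.

The social-avoidance score averages four cohort-z-scored components —
interaction-zone time ratio (trial 2 / trial 1), corner-zone ratio, and the
two trial-2 durations — with the two interaction components multiplied by
−1 so that positive always means avoidance.  Z-scoring uses the sample
(n−1) standard deviation across the *scored* cohort, which by default is
the stressed animals only: the classification is defined for defeated
animals, and pooling controls would shift every z.  Corner time sums both
corners.  Composite > 0 ⇒ susceptible, < 0 ⇒ resilient; exactly 0 is
labelled resilient with a tie flag, since only "above"/"below" are
defined.  Animals with a zero trial-1 denominator are excluded from the
z-population with a warning rather than silently propagating infinities.

The urine-marking assay calls a pair's dominant mouse only on the
conjunction of strictly more deposits *and* strictly larger marked area;
anything else is undetermined and drops from the tube-test concordance
table, which is tested with Fisher's exact test.

## 4. Statistics

Welch's *t* (unequal variances, Welch–Satterthwaite df) and Fisher's exact
test delegate to base R; the test suite checks both against independent
closed-form and enumeration oracles.  Grubbs outlier removal is applied
iteratively (remove the single most extreme point while it exceeds the
two-sided critical value at α, stop at n = 3) — whether the original
procedure iterated is unstated, and the iterative form is the common
practice the `removed` audit trail makes transparent.  Bonferroni takes an
explicit family size *m* so post-hoc contrasts can be corrected for
families larger than the vector at hand.

The group comparison for event-locked amplitudes is
`amplitude ~ group + (1 | mouse)`, REML via `lme4::lmer`: repeated events
per animal violate independence, and the random intercept carries the
between-animal variance.  Degrees of freedom are a choice lme4
deliberately refuses to make.  The default here is the between–within
approximation, df = n_mice − n_groups, the right scale for a factor that
varies between animals: in null simulations at the package's design size
(10 mice × 8 events per group) it holds the 5% level at 3.8–6.2% over
1000 replicates.  `ddf = "residual"` (df = n_events − n_groups) is also
exposed, as amplitude-per-event df conventions are common in published
reports; it is mildly anticonservative when between-animal variance is
present.  A repeated-measures two-way ANOVA contract (`rm_two_way_anova`)
delegates to `stats::aov` with a subject error stratum for
condition-by-treatment designs; it is surface area, not a re-derivation.

## 5. The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth; its defaults are fixed study conditions, not tuning knobs.

**Tube bouts** are scripted: labelled episodes (push, nose push, resist,
retreat, idle) for each actor, with kinematics chosen so the classifier's
default thresholds fire with margin — pushes and retreats move at 3 cm/s
against 2 cm/s thresholds, approach and relax phases move at 1 cm/s below
threshold, and the resting nose gap (2 cm) only closes to contact (0.5 cm)
just before a scripted contact.  Because pushing implies the partner holds
ground (and a scripted resist implies a partner push), the truth table
records these implied complements alongside the scripted events, flagged
`scripted = FALSE`, so precision can be scored against a complete truth
set.  Noise is i.i.d. Gaussian on every coordinate (default 0.05 cm;
keypoint dropout is off by default, with the confidence column emitted
as 1).  Pose runs at 30 fps — no acquisition rate is published, and 30 fps
makes the 0.2-s minimum event five frames.

**Photometry** (100 Hz; again a choice, made so the 15-Hz filter and
sub-second windows are meaningful) is
`F0 · e^(−t/τ_bleach) · (1 + Σ transients + artifact) + noise` in the
signal channel and the same without transients in the control channel.
The transient kernel is `(1 − e^(−t/0.2)) · e^(−t/1.5)`, peak-normalized —
GCaMP6s-like rise and decay; the sensor is named in the source, its
kinetics are not.  The artifact is Gaussian noise smoothed to < 1 Hz,
scaled to 2% of baseline, shared by both channels with gain ratio 1;
bleaching defaults to τ = 600 s.  The analytic mean of the kernel over
[0, 4] s is 0.4595 of peak, which is the conversion used whenever a
recovered mean amplitude is compared with an injected peak.

**OFSI trajectories** realize requested zone occupancies by construction:
zone visits are scheduled segments of a reflected random walk confined to
each zone, connected through a central band that touches no zone, so
occupancy is exact to frame count (±5% after transit effects) and each
interaction visit is exactly one entry.  The built-in profiles emulate the
three outcome groups (avoider ≈ susceptible: trial-2 interaction collapses
to 8 s with 70 s in corners; approacher ≈ resilient: 65 s interaction;
control in between), and `simulate_cohort()` attaches entry-locked
transients with group amplitudes (0.05 / 0.01 / 0 ΔF/F) plus a per-animal
offset (sd 0.005) to create the within-mouse correlation the LMM is meant
to handle.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: identity swaps and systematic (non-Gaussian)
pose errors from markerless tracking; hemodynamic or wavelength-dependent
artifacts that differ between the 405- and 470-nm channels (the shared
artifact with gain 1 is the best case for isosbestic correction);
behaviorally correlated motion artifact; occupancy profiles with gradual
zone approaches rather than scheduled visits.  Validation on synthetic
data bounds implementation error, not biological generality.

## 6. Problem sizes and runtime

The test and acceptance runs use 200 synthetic bouts for event recovery,
100 bouts of ≤ 500 frames for oracle equivalence, recordings of 600 s for
transient-recovery checks, 50 cohorts of 20 animals for avoidance
classification, and 100 + 1000 mixed-model simulations at 10 mice × 8
events per group.  These sizes put Monte-Carlo error well inside each
check's tolerance while keeping the full suite in the low minutes on one
CPU.

## 7. Known limitations

* The ethogram thresholds are conventions; on real video they must be
  calibrated against hand scoring before the rates are trusted.
* Resist is an interpretation (hold-ground-under-push) of an undefined
  label.
* Win detection by tailbase exit can mis-time a win if the tracked
  tailbase leaves the tube before the rear paws do.
* The sliding-median baseline is biased upward during dense event trains;
  amplitudes from single-channel recordings are correspondingly
  conservative.
* The LMM assumes a single random intercept per mouse; slope
  heterogeneity across sessions is not modelled.
* File-based pipeline runs expect the package's CSV layouts; photometry
  HDF5 containers are not read — convert to CSV first.
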