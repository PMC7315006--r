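---
title: "Methods: pose-to-kinematics analysis of cuttlefish pursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-to-kinematics analysis of cuttlefish pursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitkin)
```

This vignette documents the models, conventions, parameter choices and
known limitations behind `pursuitkin`. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate conventions

Pose tables arrive in image convention: origin top-left, y increasing
downward, 0-based frame indices, pixel units. All geometry is done
internally in a y-up mathematical frame (y negated), so that positive
angles are counter-clockwise and the usual trigonometric identities
hold. The rail along which the prey moves is the image x axis, with
rightward positive. Speeds are signed along this axis.

The pixel-to-millimetre calibration cannot be recovered from a pose
table, so `mm_per_px` is a required metadata field, never inferred.

## Angular variables

With nine labelled points, the derived axes are:

- **Body axis / heading**: unit vector from the dorsal mantle end to
  the head (midpoint of the two eyes). The per-trial mantle-length
  scale is the *median* over frames of |head − mantle end|, which is
  robust to the soft-body shape changes cuttlefish show while
  swimming.
- **Visual attack angle α**: signed angle from the heading to the
  head-to-prey direction. The prey reference point is the midpoint of
  the shrimp's eyes (configurable to the hook or the four-point
  centroid); strikes target the anterior body, and the hook is an
  artifact of the rig.
- **Eye angle β**: only one point per eye exists, so the "ocular
  axis" is realised as the mantle-end-to-eye vector, and β is its
  angle to the heading. This is an interpretation forced by the label
  set, not a certified operationalisation: it cannot distinguish true
  ocular rotation from a change in eye-socket position. Vergence-like
  changes appear as Δβ, the max−min excursion of β over a window.
- **Tentacular strike angle δ**: angle from the heading to the
  head-to-club-tip direction. A retracted club sits between the arms
  and its direction is label noise, so δ is reported only while the
  tip is extended beyond 0.35 ML (the *extended* predicate; retracted
  clubs in the simulator sit at 0.12 ML, clearly below, and a strike
  peaks near 1.8 ML, clearly above).
- **Club angle θ**: direction of club travel (tip displacement over a
  centred 5-frame window) relative to the tentacle axis (head-to-tip
  line). It is undefined when the tip moved less than 2 px over the
  window, since the direction of a near-zero displacement is noise.
  Late-strike changes in θ are the signature of in-flight trajectory
  correction.

All angle operations are rotation/translation equivariant and negate
under left-right mirroring; the test suite checks this against an
independent polar-angle oracle.

## Cleaning and differentiation

Coordinates with detection likelihood below 0.9 (the customary
confidence cut for this class of pose estimator) are treated as
missing; interior gaps are filled by linear interpolation in frame
index, edge gaps by constant extension so no motion is invented at
recording boundaries. Interpolation is exact for affine motion and
idempotent. An optional jump gate (displacement > J px/frame) is
available for high-confidence mislabels but is off by default, since
the study protocol describes only occlusion gating plus
interpolation.

Speeds are estimated as a central difference of the x coordinate
after a centred moving average whose window shrinks symmetrically at
the edges (default 5 frames ≈ 56 ms at 90 fps). The smoothing is
applied *inside* derivative estimation only; stored coordinates stay
raw, because positions are authoritative data and the published
protocol names no position filter. A 5-frame average preserves affine
signals exactly, so constant-velocity segments are recovered without
bias; the prey's instantaneous reversals are smeared over ±2 frames,
which is why phase-averaged speed estimates sit a fraction of a
percent below the commanded values.

## Segmentation

**Attention** is operationalised purely from body alignment: maximal
intervals with |α| ≤ 30°, interruptions shorter than 0.5 s bridged,
intervals shorter than 1 s dropped. The published attention times
were hand-scored and no thresholds exist to match, so this rule is a
documented reconstruction with every threshold exposed in
`pipeline_config()`; episode-level statistics are therefore validated
against the packaged reference table rather than against
re-detection.

**Strikes** are detected per side as an upward crossing of the
normalised extension e(t) = |tip − head| / ML through 0.5 ML with
de/dt ≥ 2 ML/s (the rate condition rejects slow drifts), lasting
until e falls back below threshold. The tentacles are shot as a pair,
so bilateral detections with onsets within 100 ms merge into one
event. Strike *success* is never inferred from kinematics — five
tracked points cannot resolve contact — it comes from the simulator's
ground truth or a manual annotation column.

**Prey phases** are labelled stationary (|v| < 5 mm/s), slow
(5–50 mm/s) or fast (≥ 50 mm/s), median-filtered over 5 frames;
reversals are sign changes of the speed between non-stationary
frames. The 50 mm/s split is the midpoint of the rig's two commanded
speeds.

## Rank statistics

The paired signed-rank test and the Mann–Whitney U test are
implemented with explicit exact/approximate semantics: exact
enumeration of the permutation null (all 2^n sign assignments, or all
C(N, n1) group labelings, over midranks, so ties are handled
naturally) up to n = 15 informative pairs / N = 20 total; beyond
that, the normal approximation with tie and continuity corrections.
Two-sidedness is defined as |statistic − null mean| at least as
extreme as observed. These switchover points mirror common
statistical-package defaults; in particular the 29-episode
attention-time comparison (n = 10 vs 19) uses the
continuity-corrected normal approximation, which is the variant that
reproduces the published p-value to four decimals (the exact
enumeration gives 0.104).

The "spread against a norm" comparisons (distance against 1 ML,
angle against perpendicular) are provided as a one-sample sign-flip
location test, clearly labelled a reconstruction: the original
variant behind those printed values is not recoverable, and they are
excluded from any quantitative validation here.

## The simulator

The generator's defaults *are* the study conditions: 120 s sessions
at 90 fps, 2048×2048 px frames, a 250 mm rail traversed at 25 mm/s
leftward and 75 mm/s rightward with instantaneous reversals (the rig
reverses "suddenly"; no acceleration ramp is modelled), a cuttlefish
with an 80 mm mantle (mid-range of the 6–10 cm animals), 0.5 mm/px
calibration, 1 px coordinate noise and 2% occlusion. Values the
protocol does not state were chosen once as field-plausible and are
documented here: the 150 ms sensorimotor delay (order of visuomotor
latencies in fast invertebrate predators), the 100 mm standoff from
the rail, the 120 ms strike duration (consistent with sub-second
seizure timing), and the 5 mm success radius (order of a shrimp body
width) — all exposed as scenario fields, none tuned.

The agent encodes the study's behavioural findings as mechanism so
that downstream statistics have signal: during attention windows its
horizontal velocity tracks the *delayed* prey velocity scaled by a
phase-dependent pursuit gain (defaults 0.9 slow / 0.05 fast — it
keeps up with slow prey and all but freezes for fast prey), and its
heading turns toward the prey at up to 90°/s. Outside attention it
is stationary with its heading held 90° off-prey. Because the gains
are asymmetric, the agent drifts leftward over successive rail
cycles; this is a deliberate consequence of pure velocity-matching,
so scripted strikes are best commanded inside attention windows when
the prey passes within reach.

Strikes freeze the agent's translation and extend the tips
ballistically to the aim point — the delayed observed prey position,
extrapolated by delay × prey velocity when *predictive* — capped at
the commanded peak extension, then retract over the same duration. A
terminal correction rotates the club bearing over the final 30% of
the extension. With matching delay and constant prey velocity,
extrapolation cancels the delay by construction and the only miss
component is the prey's travel during the strike itself; a
non-predictive strike on fast prey misses by roughly speed × delay
and fails.

For scripted-attention recovery tests the scenario uses a saccadic
turn rate (450°/s): orienting is a rapid body saccade, and with the
default 90°/s the 60° swing from the off-attention posture into the
30° detection gate would itself take two-thirds of a second,
swamping the boundary measurement.

What the simulator does **not** emulate: pixel imagery (poses are
rendered directly, so estimator-specific error structure such as
identity swaps or water-ripple distortion is absent), body
deformation (the mantle length is rigid), 3-D posture, and prey
behaviour beyond the rig's 1-D protocol. Passing parameter-recovery
tests therefore demonstrates that the pipeline's inference is correct
for data matching its observation model, not that the pose estimator
itself is reliable on real video.

## Problem sizes and numerical choices

The test suite works at desk scale by choice: most simulated trials
run 10–40 s (900–3600 frames); the strike-detection sweep uses 100
seeded 20 s trials with two strikes each; speed recovery uses the
full default 120 s session. Exact-enumeration cross-checks cap at
n ≤ 10 (≤ 252 labelings), where exhaustive oracles are instant.

Degenerate inputs fail loudly: zero-length vectors in any angle
operation, a mantle end coinciding with the head, a body part missing
in every frame, all-zero paired differences. Angles live in
(−180°, 180°], with the −180° branch mapped to +180°. The
`(start, end)` convention for episodes is end-exclusive in frames, so
a fully-aligned session yields an episode exactly as long as the
session.

## Known limitations

- β is a positional proxy; real ocular rotation is unobservable from
  one point per eye.
- Attention detection reflects body alignment only; an aligned but
  inattentive animal is indistinguishable.
- The published per-trial velocity statistics and eye-excursion
  values from the original videos cannot be recomputed without those
  recordings; the pipeline reproduces their *form* (the same tables
  and tests) on simulated data with known ground truth.
- Whether the "horizontal distance" in tracking figures is cumulative
  path or displacement is ambiguous in the source; displacement from
  episode start is used.
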