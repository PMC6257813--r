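---
title: "Simulating spatialized-audio navigation: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spatialized-audio navigation: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audionav)
```

`audionav` simulates an augmented-audio navigation assistant and its blind
users at desk scale. This vignette is the package's own account of the
science inside it: the models and their assumptions, the parameters that
matter, what a green test establishes, and the choices we made where the
design was genuinely open.

## 1. Geometry and conventions

Coordinates are right-handed, x/y horizontal, z up. Yaw is measured from
the +x axis, **positive clockwise seen from above**, so that a positive
relative azimuth is to the listener's right and a left-to-right scan visits
objects in ascending azimuth. Azimuths live on (−180, 180], computed in the
horizontal plane only — elevation is ignored throughout, consistent with
azimuth-only aiming analyses. The spotlight cone is measured in azimuth and
its boundary is inclusive: a source at exactly half the aperture speaks,
which avoids on/off flicker in discrete time when a user holds the boundary.

Obstacles are a 2D occupancy grid (default cell 0.1 m) standing in for a
scanned 3D mesh; distance to an obstacle is the distance to the nearest
blocked cell's boundary. Stairs are annotations on waypoints, not geometry:
a simulated walker's height is the height of the horizontally nearest path
point. These simplifications keep every quantity testable by brute force
(the suite checks obstacle distances and path costs against exhaustive
oracles on small grids).

## 2. Sonification

Object voices carry a pitch multiplier `min(c, d_ref/d)`. The published
description fixes only "pitch increases inversely with distance"; the
functional form, the reference distance `d_ref = 2` m (the canonical task
distance, factor 1 there) and the clamp `c = 4` are this package's choices —
bounded, monotone, and matching the verbal description. The collision hiss
threshold (0.7 m ≈ arm's length plus a step) is likewise unpublished and is
a configuration knob; the hiss is emitted strictly *below* the threshold so
that a wall at exactly the threshold is silent.

The raw-sonification baseline encodes a grayscale image as a spectrogram
scan: column *j* plays at time `j/(cols−1) · scan_duration`, row *i* maps to
a log-spaced frequency in 500–5000 Hz (top row highest), brightness is
amplitude. Scan duration 1 s. These follow the common convention for
image-to-sound substitution; none are published values. The encoder is
linear in brightness (property-tested) and an optional waveform renderer
sums amplitude-weighted sinusoids per column.

## 3. The virtual guide

The guide is a state machine over an arc-length-parameterized polyline. Per
time step it (a) advances at up to 1.2 m/s while the user is within 1 m
(Euclidean), capped at 1 m of along-path lead; (b) accumulates a call timer
and emits "follow me" every 2 s; (c) announces each intermediate waypoint's
turn/stairs annotation exactly once when the user's along-path progress
comes within 2 m of it; (d) declares arrival within 1.2 m (inclusive) of
the final waypoint. The 2 m instruction lead is a design choice — far
enough to precede the turn at normal walking speed — and is exposed as
`instruction_lead` because users report that earlier timing can help.

Two questions the published description leaves open:

* **"1 m ahead" along-path or Euclidean?** Along-path, for the lead cap;
  Euclidean for the advance condition (both rules are stated separately).
* **What is the user's along-path position?** The raw nearest-point
  projection is *discontinuous* wherever a corner-cutting user crosses a
  corner bisector (jumps of ~1 m on the bundled path), so no controller
  could bound the raw projected lead. The guide therefore tracks a
  monotone, locally windowed **station** (the standard device in
  path-following control): the projection is restricted to ±1.5 m of arc
  around the previous station and never decreases. The lead rule, the
  instruction triggers and the acceptance assertions all use this station.
  If the user physically retreats, the guide falls back so its lead over
  the station never exceeds 1 m; its behavior when overtaken is otherwise
  unspecified and unmodeled.

Automated wayfinding runs A* on the occupancy grid: 8-connected, straight
steps cost one cell and diagonal steps √2, with diagonals disallowed when
either adjacent orthogonal cell is blocked (no corner clipping). The cell
chain is simplified to waypoints at direction changes and turns are
annotated by cross-product sign. The suite equates its cost with an
independent value-iteration oracle on 200 random grids up to 50×50; a
breadth-first oracle would be wrong here because the edges are weighted.

## 4. The user model

A percept of a source at true relative azimuth θ is

> mirror the azimuth about the interaural axis with probability
> `fb_confusion_prob`, then add `bias_deg` and `N(0, noise_sd_deg)`, then
> wrap.

Gaussian azimuth noise is an assumption — only per-subject bias and s.d.
are published (bias −9…+13°, s.d. 3–12°, which the presets and acceptance
profiles span). The front–back mirror is the standard model for the
observed wrong-direction starts; its default rate 0.036 ≈ 5/139 is a
calibration from the published trial counts, not ground truth.

**Direct navigation policy.** Two phases, as observed in subjects: ORIENT
(click every 0.5 s, turn toward the percept, confirm once a post-turn
percept is inside the 10° aim tolerance) and WALK (1.2 m/s, re-clicking and
correcting heading; a percept beyond 90° drops back to ORIENT, which is how
a reversed start recovers). Walk speed, turn speed (90°/s), tolerance and
click interval are all profile fields; the recovery threshold is a free
parameter because subjects' mid-walk re-orientation criteria are not
described.

Two endgame details exist for estimator correctness and are worth knowing:

* The recorded aiming error is taken after one **final fine-tuning turn**
  made from a fresh percept while the voice command registers. Without it,
  the error is a draw *conditioned on two consecutive percepts agreeing*,
  which deflates the recovered noise s.d. by ~25% at σ = 12° and breaks
  parameter recovery. With it, the recorded error is an unconditioned draw
  of bias + noise, and `aiming_stats()` over 21 trials recovers both
  parameters within 3 standard errors ≥ 95% of the time.
* That final percept is drawn **without front–back confusion**: by
  confirmation time the subject's accumulated head movements have resolved
  the ambiguity (the classic disambiguation account). Reversals remain
  fully active while walking. Without this, ~3.6% of aiming trials would
  register ~180° off — outliers absent from the published aiming data.

**Guide following.** The agent steers toward the latest "follow me" percept
at walking speed, estimates the caller's range from the call's pitch,
pauses when it believes it has reached the caller, when its heading is
>60° off (turn in place), or after >4 s of silence. Corner cutting — and
hence negative per-segment deviation indices — emerges naturally from
steering at a guide that is already past the corner; there is no explicit
corner-cut parameter.

**Memory.** Exploration stores one azimuth per heard object with encoding
noise equal to the localization noise; recall adds `N(0, 15°)` by default,
calibrated so recall errors are ~15° rms as measured. Both layers are this
package's construct — only recall outcomes are published — so with nonzero
encoding noise the total rms slightly exceeds the recall figure.

**Cane baseline.** An uninformed correlated random walk with wall
reflection at half walking pace. The published cane-search outcome ratios
(8× time, 13× distance) depend on real human search behavior and are
deliberately not asserted anywhere.

## 5. Tasks and logging

All task geometry defaults to the published protocol: localization target
at 1 m, uniform azimuth, 21 trials (the Results text says 2 m where the
Methods say 1 m; we default to the Methods value and expose it); five
memory objects at −60°…+60° in 30° steps at 2 m, 60 s spotlight
exploration, two blocks with the two printed label orders, the center
object never queried (a ±7.5° sonar-beep sector marks straight ahead);
direct navigation to a chair at 2 m in one of four quadrants, complete
within 0.5 m, 20 trials; guided navigation along the bundled nine-waypoint
36.4 m building path (lobby / stairwell / hallway segments) starting within
1.2 m of the first waypoint; three VR benchmark tasks in a 10×10 m living
room with 16 objects, 20 trials, 60 s limit, termination after five
consecutive failures, and the key task's dual completion rule (head within
1 m *and* facing within 30°).

Poses are logged at exactly 5 Hz; the simulation substep is finer (50 Hz
for walking tasks, 10 Hz for pure rotations) and decimated. Trials end with
a 2 s stationary tail while the arrival feedback plays. That tail is an
estimator-correctness decision: a trajectory truncated mid-stride at the
trigger-zone boundary loses ~0.5 m under the 2 s moving average, and a
noiseless trial would read DI ≈ −0.5 instead of ≈ 0. The per-trial time
limit of 120 s for the non-benchmark tasks is not published; it merely
bounds the simulation.

## 6. Analytics

The measurement pipeline is: 2 s centered moving average (shrinking windows
at the edges, preserving series length — edge handling is unpublished and
this choice keeps endpoints defined); path length as the sum of successive
displacement norms (2D for planar tasks, 3D for guided navigation);
navigation-phase onset at the first sample whose distance to target has
changed by 0.3 m in *absolute* value, so wrong-direction starts count;
`DI = (L_exp − L_ref)/L_ref` with `L_ref` the straight line from the onset
position to the trigger-zone boundary (direct navigation) or the guide-path
length (guided navigation); walking speed as the 90th percentile of
frame-wise speeds (robust to orientation pauses), normalized by
free-walking speed; aiming errors read 1 s before the end of memory-task
trials (voice-command delay) and at the end otherwise.

Aiming bias and accuracy are **circular** mean and s.d. — below ~30° of
dispersion these agree with the linear statistics to a fraction of a
degree, and circular is safe for wrapped data. The Rayleigh test uses
`z = n·R̄²` with the standard series approximation for p, clamped to
[0, 1]; its type-I error at n = 20 is calibrated to 0.05 ± 0.01 over 10⁴
null replicates in the acceptance suite.

## 7. What a green test does and does not establish

The synthetic agents reproduce the *structure* of the published findings:
localization bias/accuracy in the measured ranges, essentially straight
direct-navigation trajectories 2–12% long (the published human range is
11–25%, which our simpler kinematics undercut except at the noisiest
profiles — humans decelerate, overshoot and sway), arrival on the guided
path with segment-level corner cutting, recall regressions near the
identity, and near-chance raw-sonification performance (uniform aiming by
Rayleigh test). They do **not** model gait dynamics, deceleration, head
sway (the smoothing exists to remove a component our agents barely
produce), elevation perception, real HRTF acoustics, speech recognition, or
fatigue; published human absolute durations (e.g. ~119 s for the guided
route) are therefore not targets, and the cane-search outcome ratios are
reported-only. Seeded runs replay bit-identically; every stochastic claim
in the acceptance suite is a property of the stated parameter ranges, with
seeds fixed before outcomes were inspected and thresholds taken from the
published bounds.

## 8. Numerical choices

* Angle wrapping maps to (−180, 180] exactly; −180 is normalized to +180.
* Boundary rules: spotlight inclusive, arrival inclusive (asserted at a
  binary-exact 1.2 m), collision warning strict, trigger zone inclusive.
* The A* octile heuristic `max + (√2−1)·min` is consistent, so closed
  nodes are never reopened.
* Ties in scan order break lexicographically by object id, making event
  schedules deterministic.
* The noiseless direct-navigation DI is asserted at |DI| ≤ 0.02: the
  dominant discretization is the 0.5 s perception update (heading may be
  up to the 10° tolerance off when walking starts), not the 20 ms motion
  step.
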