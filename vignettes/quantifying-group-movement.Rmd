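---
title: "Quantifying spontaneous group movement from 2-D position data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spontaneous group movement from 2-D position data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupmotion)
```

## Scope

`groupmotion` quantifies how a group of free-running individuals — the
motivating case is nursery-school children running in a hall during a
music-education warm-up — moves collectively, from nothing but 2-D position
time series. It provides the full chain: trajectory ingestion and
calibration, collective-motion indices, approach-event analysis,
per-individual histogram statistics with a between-class test, and an
agent-based generator used to validate the chain end-to-end.

This vignette documents the model, the estimators, the numerical choices,
and the design rationale of the synthetic-data generator.

## Data model

A session is a `trajectory_set`: an array `pos[frame, individual, (x, y)]`
in centimetres on a uniform frame grid (default 0.05 s). Raw digitized
positions, typically sampled at a coarser interval (e.g. 0.2 s) with
occasional missing samples, are brought onto this grid by
`resample_spline()`, which fits one interpolating cubic spline per
individual and coordinate. If the floor coordinates were digitized from an
oblique camera view, `fit_projective_transform()` estimates the plane
homography from four or more reference points (a hand-written linear solve
of the 8-parameter direct linear transform) and `calibrate_session()`
applies it.

Two numerical choices deserve justification:

* **Spline end conditions.** The default is `method = "fmm"`
  (Forsythe–Malcolm–Moler), which reproduces polynomials up to cubics
  exactly, including at the ends of the series. Natural end conditions
  (zero second derivative at the boundary) are selectable but bias the
  boundary segments of smooth trajectories; the test suite's
  parabola-reproduction check only holds with `"fmm"`.

* **Velocity estimation.** `compute_velocity()` uses backward differences
  by default: `v(t) = (c(t) − c(t−1)) / dt`, so the velocity at a frame
  describes the displacement *arriving* at it and the first frame has no
  velocity. This matches the convention that an approach-onset frame's
  look-back window is evaluated with velocities that do not peek forward in
  time. Central differences are available as an option; for smooth motion
  both agree to first order, and the test suite bounds the circular-motion
  error of the backward scheme by `0.5 R ω² dt`.

## Movement indices

All indices live in `movement_indices.R` and are validated against
brute-force double-loop oracles to 1e-9.

* **Pairwise distance** `pair_distance()`: Euclidean distance per frame and
  unordered pair.

* **Heading angle** `pair_angle()`: for the ordered pair (i, j), the angle
  in `[0°, 180°]` between i's velocity and the displacement from i to j.
  The cosine is clipped to `[−1, 1]` before `acos()` to absorb round-off;
  frames with zero speed or coincident positions are `NA` rather than an
  arbitrary angle.

* **Angular momentum** `angular_momentum()`: per individual and frame, the
  magnitude of the 2-D cross product of the unit radial vector (position
  relative to the *static group centre*) and the unit velocity vector —
  `|sin φ|` in `[0, 1]`, where 1 is pure rotation about the centre and 0
  pure radial motion. The static group centre, `static_group_center()`, is
  the session-mean of the per-frame centroid; using a fixed centre makes
  the index an order parameter of large-scale rotation rather than of
  local swirling.

* **Activity amount** `activity_amount()`: mean speed per individual, and
  `group_angular_momentum()`: the per-frame mean of the valid individual
  momenta.

## Approach events and approaching angles

`detect_events()` marks an approach onset at the first downward crossing of
the 50 cm threshold — frame `t` with `d(t) < 50` and `d(t−1) ≥ 50` — the
personal-space distance used throughout. For each onset,
`approach_angles()` samples the heading angle in look-back windows before
the onset (defaults 0–1 s, 1–2 s, 2–3 s). A window `[lo, hi]` seconds
before onset frame `t0` is the half-open frame range
`[t0 − hi/dt, t0 − lo/dt)`, so adjacent windows partition frames without
overlap. Samples are restricted to frames where the pair distance lies in
`[100, 200)` cm — far enough that the angle measures intent rather than
collision geometry, close enough to be relevant to the upcoming contact.
Both members of a crossing pair are evaluated as potential approachers; the
band gate and the velocity requirement naturally filter the passive member.
Every emitted sample carries its provenance (onset frame, sample frame,
distance), so the gating is re-checkable after the fact.

`approach_matrix()` aggregates directed samples into a row-normalized
matrix: cell (i, j) is the fraction of approacher i's angle samples, over
all targets, that fall in the (10°, 20°] bin and are aimed at j. Whether
per-frame samples or per-event summaries are the right unit, and how the
matrix should be normalized, are interpretation choices; both the bin and
the window are arguments, and rows with no samples are all-zero rather than
renormalized.

## Histogram statistics

Each individual contributes a *normalized* histogram — bin counts divided
by that individual's total sample count — so children observed for
different durations contribute comparable probability vectors. Bin
families (`bin_spec()`): distance in 50 cm bins from 0 to 1350 cm plus an
overflow bin that enters the normalization but is never tested; heading and
approaching angle in 18 bins of 10°; angular momentum in 10 bins of 0.1.
Bins are right-closed with the first bin closed on both sides, so 0 falls
in the first bin, and a bin is labelled by its upper edge ("the 50 cm
bin", "the 0.8 bin").

`compare_classes()` runs, per bin, a pooled-variance two-sample Student
t-test on the per-individual frequencies with `df = n_a + n_b − 2`,
multiplies p-values by the family size (Bonferroni, capped at 1), and
reports the pooled-SD standardized mean difference as the effect size.
The effect size deliberately omits the small-sample J correction, which
makes the identity `|g| = |t|·sqrt(1/n_a + 1/n_b)` exact; the test suite
checks this identity on every emitted comparison. Class A is always first,
so negative t means class B sits higher in that bin. Zero pooled variance
with equal means yields `t = 0, p = 1`; with unequal means it is flagged
as `±Inf` rather than silently dropped.

## The synthetic-data generator

Since sessions of real children cannot be re-collected at will, the
package ships an agent-based generator (`simulate_rotation()`,
`simulate_tag()`, `simulate_mixed()`) whose two regimes emulate the two
observed behaviours, and whose ground truth (role assignments, contact
events) lets the analysis chain be validated by parameter recovery. The
generator's defaults are the study conditions: a 1000 × 850 cm hall,
0.05 s frames, running speeds around 200 ± 40 cm/s, group sizes of about
11–13.

**Rotation regime.** Agents run on concentric rings around the hall
centre. Initial phases are balanced — antipodal pairs, plus one
equilateral triple when the count is odd — so the group centroid starts at
the ring centre and stays there in expectation; with heading noise off the
per-frame centroid is exactly the centre and every agent's angular
momentum is 1 up to discretization. Each step aims at the next point of
the agent's *fixed* home circle before heading noise is added, which makes
the radius self-correcting: noise perturbs the path but cannot let ring
radii random-walk into each other. Ring radii span 14–45 % of the shorter
hall dimension.

**Tag regime.** One agent is the chaser and runs 1.4× faster (children
sprint when "it"); its heading relaxes toward the line of sight to its
target (gain 0.5 per frame). All players within 200 cm of the chaser flee
(gain 0.25), and players straying more than 250 cm from the playing
group's centroid steer back toward it (gain 0.1), keeping the game loosely
clustered the way a real game stays inside a social huddle. On contact
(< 50 cm) the roles switch and the new chaser draws a random target.
Walls reflect. Every contact is logged with frame, chaser and target, and
the test suite re-checks each logged contact against the positions.

`simulate_mixed(p_social)` assigns each agent to the pursuit game with
probability `p_social` and delegates exactly — `p_social = 0` is
bit-identical to `simulate_rotation()`, `p_social = 1` to
`simulate_tag()` — so intermediate mixtures interpolate between the
regimes. All randomness flows from a single integer seed; identical seed
and configuration give byte-identical output.

**What the generator does and does not emulate.** It reproduces the
*kinematic signatures* of the two regimes — high sustained angular
momentum for rotation; frequent sub-50 cm passes, head-on look-back angles
concentrated just before onset, and depressed angular momentum for tag.
It does not model decision making, anticipation of escape directions,
fatigue, or the social structure of who chases whom, and its agents are
points without bodies, so contact is a distance threshold rather than a
physical touch.

## Validation design

Three layers of tests guard the chain:

1. **Oracles and closed forms.** Every index is checked against an
   independent double-loop implementation on random trajectories, and
   against exact geometric cases (tangential motion ⇒ momentum 1, head-on
   pursuit ⇒ approaching angle 0, uniform samples ⇒ uniform histogram).

2. **Parameter recovery.** Simulated rotation (12 agents) vs tag
   (11 agents) classes of 40 s must yield Bonferroni-significant
   differences in the 50 cm distance bin (tag higher) and the top angular
   momentum bin (rotation higher) in at least 80 % of 50 seeded
   replicates.

3. **Null calibration.** With the *same* generator for both classes
   (rotation vs rotation, 1000 replicates), the family-wise false-positive
   rate of each bin family must stay within three binomial standard errors
   of the nominal 5 %. The two classes of a null replicate are two
   independently seeded sessions, mirroring how real sessions are
   independent groups of children; a design that split one session's
   children into pseudo-classes would share session-level randomness
   across arms and misstate the error rate.

## Limitations

* The per-bin t-tests treat children within a class as independent units;
  children within one session share the session's dynamics, so with few
  sessions per class the effective sample size is optimistic. The original
  design (single sessions per class) has the same property.
* Bonferroni over 27 or 18 bins is conservative, and adjacent bins of one
  individual's histogram are negatively coupled by the normalization.
* The approaching-angle analysis conditions on events that the distance
  threshold itself defines; threshold, band and windows are arguments
  precisely because these choices are interpretive.
* Spline resampling bridges short gaps but cannot recover long occlusions;
  individuals missing more than 10 % of samples are excluded with a
  warning rather than interpolated.
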