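---
title: "Simulating passive exotendon assistance of harvesting pulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating passive exotendon assistance of harvesting pulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exotendon)
```

## The question and the model

Repetitive loaded pulling — cutting oil-palm fruit bunches with a sickle —
places large demands on the lumbar extensors. A passive exotendon is an
elastic band routed in parallel with a muscle: it generates tension only
when stretched beyond its resting length, so it can shoulder part of a
muscle's work without actuation. This package simulates where to place
such a device (which host muscle), and with which resting length and
stiffness, on a reduced musculoskeletal model of the harvesting pull.

The model is deliberately desk-scale: nine rigid segments (a fixed pelvis
base, torso, head, and paired upper arms, forearms and hands) articulated
by eleven generalized coordinates — a 3-DOF lumbosacral joint
(flexion–extension, lateral bending, axial rotation), 3-DOF shoulders and
1-DOF elbows. This preserves every reported joint-moment panel while
avoiding the cost of a full-spine model; the spinal rhythm that
distributes trunk motion over several intervertebral joints is explicitly
out of scope. Segment masses are anthropometric fractions of the subject
mass (default 56.83 kg, the mean of the harvester cohort the task
emulates); flexion, rightward bending, adduction and rightward rotation
are positive. Because anatomical flexion rotates the trunk and a hanging
limb in opposite world directions, the shoulder and elbow flexion axes are
the mirror of the trunk's.

### Muscles

Eighteen Hill-type fascicles cover the muscle groups recruited by
harvesting: longissimus (L1, R11, T9) and iliocostalis (R10, R11, R12)
fascicles of the erector spinae, multifidus, quadratus lumborum, rectus
abdominis, external and internal obliques, psoas major, and paired
latissimus dorsi, biceps and triceps. Muscle geometry is polynomial: each
fascicle's musculotendon path length is a degree-≤2 polynomial of the
coordinates it spans, so moment arms (`r = −∂L/∂q`, tendon-excursion
convention) are analytic and exactly consistent with the path lengths.
Published models do not constrain this geometry at desk scale, and
polynomial paths make every derivative testable against finite
differences.

Available muscle force is `a · F⁰ · fl(l̃) · fv(ṽ)` with a rigid tendon
(fiber length = path length − tendon slack length), a Gaussian active
force–length curve `fl(l̃) = exp(−(l̃ − 1)²/0.45)` on normalized fiber
length, and a Hill force–velocity factor normalized to 1 at zero velocity,
0 at maximal shortening (`v_max = 10 L_o^M`/s) and saturating at 1.8 in
lengthening, with matched slopes at `v = 0`. These are the conventional
curve shapes; the source models' exact Hill constants are not published,
so the curves are fixture choices, not reference values. Passive fiber
force is omitted: the reserve actuators absorb passive joint moments in
this accounting.

The seven device host fascicles carry optimal fiber lengths `L_o^M` and
tendon slack lengths `L_s^T` back-solved so that the two published
resting-length rules,

* `L_r1 = 0.4 · L_o^M + L_s^T` (tendon transmits force from its slack
  length; the fiber produces active force from 40 % of optimal length),
* `L_r2 = L_o^M` (passive fiber force begins at optimal fiber length),

evaluate to the published device resting lengths — e.g. rectus abdominis
(0.30, 0.08) m gives `L_r1 = 0.20` and `L_r2 = 0.30` m, and iliocostalis
R10 satisfies `L_s^T = 0.6 L_o^M` exactly, making the two rules coincide
(0.16 m) and all downstream results bit-identical — a useful invariant
check. Neutral-pose path lengths equal `L_s^T + L_o^M` (fibers at optimal
length standing upright), which means both resting-length rules leave the
device pre-tensioned in the neutral pose; this is a direct consequence of
sharing the host's path and the published resting lengths.

### The exotendon

The device is a massless force element sharing its host fascicle's path
exactly (it acts in parallel, so length and moment arms are identical):

```
T = K · s · (1 + D · L̇),   s = max(0, L − L₀)
```

with stiffness `K` (N/m), dissipation `D = 0.01 s/m` and resting length
`L₀` from one of the rules above. Tension is floored at zero — an elastic
band cannot push, so a fast-shortening state cannot make `(1 + D·L̇)`
drive the tension negative. Only one device is attached per simulation.

```{r exo}
m <- build_default_model()
resting_length(m$fascicles$rectus_abdominis, "LR1")
resting_length(m$fascicles$rectus_abdominis, "LR2")
exotendon_tension(list(stiffness = 1e4, resting_length = 0.3,
                       dissipation = 0.01), L = 0.31, Ldot = 1)
```

## The synthetic sessions

No public recording of harvester kinematics exists, so the generator is a
first-class, tested module that emulates the instrumented trials: six
body-worn orientation sensors (sternum, lumbar, both upper arms, both
wrists) reporting unit quaternions, repeated sagittal-dominant pulls, and
calibrated orientations (identity in the neutral pose — the stand-still
calibration step of a field protocol is thereby sidestepped).

A pull is a minimum-jerk interpolation (`10τ³ − 15τ⁴ + 6τ⁵`, analytic
derivatives, zero end velocity and acceleration) between a start and an
end posture. The default profile — back flexion 20°→40°, shoulder flexion
30°→64°, elbow flexion 90°→40° over 1.2 s — is a fixture choice; only the
64° arm-elevation ceiling is a reported bound and is enforced as a cap.
Sessions concatenate `n` pulls (default 5) with per-pull duration jitter
(±10 %), a slower return stroke (70 % of the pull duration) and 0.5 s rest
pauses, then perturb every quaternion by a small rotation with a uniform
random axis and half-normal angle (`σ` default 0.5°; field units'
noise spectra are not published). Everything is seeded and reproducible
bit-for-bit. The default sampling rate is 100 Hz — the pipeline is
rate-agnostic and accepts the 1000 Hz of field recordings via `rate`.

What the generator does **not** emulate: sensor-to-segment misalignment,
orientation drift, soft-tissue artefact, inter-subject anthropometric
variation, and the kinematic richness of real pulls (lateral bending and
axial rotation stay near zero in the default profile). Green tests
therefore certify the pipeline's internal consistency on idealized data,
not field accuracy.

## Pipeline choices

* **Filtering.** 4th-order Butterworth low-pass, 6 Hz cut-off, applied
  forward and backward: zero phase lag (peak timing is preserved; the
  effective order doubles) and unit DC gain. The series is demeaned and
  odd-reflected at both ends (pad length `6·fs/fc` samples) so start-up
  transients decay inside the padding. By default the quaternion
  components are filtered (then renormalized) *before* inverse
  kinematics, matching a filter-the-raw-signals protocol; filtering the
  solved coordinates instead is available via the same function.
* **Inverse kinematics.** Per frame, damped Gauss–Newton on the weighted
  sum of squared geodesic angles between measured and model sensor
  orientations (default weight 1 per sensor). Numeric central-difference
  Jacobians; the damping factor backtracks until the objective decreases,
  so the objective is non-increasing by construction; coordinates are
  clipped to their ranges. Frames are warm-started from the previous
  solution (independent solves agree to < 0.05° on clean data and are
  available via `warm_start = FALSE`). Velocities and accelerations come
  from central differences of the low-pass-filtered coordinates.
* **Pull segmentation.** The activity signal is the right
  shoulder-flexion angular velocity (positive during the reach). A
  segment opens above 80 % and closes below 20 % of the session's 95th
  percentile, is extended outward to the 1 % level, and must last 0.3 s.
  On clean generator output this recovers every pull with boundaries
  within 50 ms of ground truth.
* **Representative pull.** Each detected pull is linearly resampled onto
  101 normalized-time points (the conventional 0–100 % cycle) and
  averaged pointwise; the result spans the mean pull duration.
* **Inverse dynamics.** Recursive Newton–Euler over the segment tree
  (gravity via the standard fictitious base acceleration; world frame
  Z-up, g = 9.81 m/s²). The default external load is 164 N per hand — the
  328 N harvesting force split equally — along a unit vector 60° below
  horizontal, backward in the sagittal plane, applied at the hand origins
  and held constant across the representative pull (the load's true time
  course within a pull is not documented). Forward dynamics assembles the
  mass matrix from unit-acceleration inverse-dynamics columns, so the
  inverse/forward pair is consistent by construction and serves as a
  round-trip oracle (residuals < 1e−8 rad/s²).
* **Static optimization.** Per frame, a convex QP: minimize squared
  activations plus squared normalized reserve torques subject to moment
  balance, `0 ≤ a ≤ 1`, reserves unbounded but penalized by
  `(τ_r/30 N m)²` (the optimal-force convention; whether the reference
  implementation bounded its reserves is not documented, so
  unbounded-with-penalty was chosen). The exotendon is passive — its
  tension depends only on the kinematic state — so it enters as a fixed
  left-hand-side contribution, never as a decision variable. The QP is
  solved with an active-set method and the detected active set is then
  re-solved exactly through its KKT system, driving moment-balance
  residuals to ~1e−12 N m (tolerance asserted: 1e−6). Degenerate optima
  inherit the solver's deterministic variable ordering. An independent
  brute-force oracle (zooming grid at 1e−3 resolution with penalty
  continuation) verifies the QP on small instances.

## Evaluation conventions

Peaks are taken over the representative pull (averaging precedes
analysis). Joint moments are normalized to body mass (N m/kg); fascicle
activations are aggregated by summation into group activations; activation
and force percentages are normalized to the subject's cross-condition
maximum per group (the analogue of a per-subject maximum across trials).
Reductions are `100·(unassisted − assisted)/unassisted`, positive =
decrease. The sweep runs all seven hosts over `{L_r1, L_r2} × {1, 10}`
kN/m; `sweep_select()` maximizes the mean reduction pooled over activation
and force of the muscles with a significant unassisted baseline (≥ 5 % of
the largest unassisted group peak — changes are only meaningful for
muscles that were active unassisted), breaking exact ties toward `L_r2`
and the higher stiffness. ANOVA is the classical between/within
decomposition; Tukey–Kramer uses `q = |Δmean| / sqrt((MSE/2)(1/nᵢ+1/nⱼ))`
against studentized-range quantiles from R's `ptukey`/`qtukey` at
α = 0.05, applied within each metric family only. When replicate runs
(seeded repetitions standing in for subjects) are supplied to
`build_report()`, each condition's per-replicate peaks form the ANOVA
groups.

```{r stats}
one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8)))[c("F", "p")]
```

## Problem sizes and determinism

The worked examples and the acceptance script use 5 pulls per session at
100 Hz with σ = 0.5° noise, a 101-point representative pull, and three
seeded repetitions where replicate averaging is called for; these sizes
were chosen so a complete scenario solves in well under a minute on one
core while exercising every stage at full fidelity. All randomness flows
from a single integer seed; repeated runs are bit-identical.

## Known limitations

* The device cannot change the motion: kinematics and net joint moments
  are held fixed, and the exotendon only redistributes how the moments
  are met. In particular, a device hosted on the antagonist of the
  dominant demand (the rectus abdominis under the extension-dominant
  default load) adds pre-tensioned antagonist moment at every taut frame
  and therefore *increases* extensor activation in this model class —
  a full-spine model with 3-D device geometry, where the device also
  spans lateral bending and rotation and alters the inverse-dynamics
  moments themselves, can behave differently. The package reports this
  honestly rather than emulating it.
* Under the extension-dominant default load the unassisted abdominal
  activations are structurally zero, so reduction percentages for those
  muscles divide by a near-zero baseline; tables report them as computed,
  and the sweep selection excludes insignificant baselines (above).
* Reserve actuators absorb whatever the 18 fascicles cannot produce;
  their share is audited (`reserve_audit()`), and at the back
  flexion–extension coordinate stays well inside the expected envelope,
  but shoulder-coordinate reserves are large because the reduced model
  carries no deltoid.
* No activation dynamics, tendon compliance, muscle wrapping, contact, or
  closed loops; orientation-only IK (no marker positions); no
  outlier-pull rejection or time warping beyond linear normalization.
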