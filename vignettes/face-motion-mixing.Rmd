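---
title: "Simulating and analysing face-motion mixing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing face-motion mixing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agencymix)
```

## The paradigm

`agencymix` implements an analysis pipeline for *face-motion mixing*
experiments on the sense of agency. In this paradigm a participant watches
an animated face — either their own or another person's — whose motion is
driven in real time by facial-landmark displacement fields. Control is
manipulated by convex mixing: under *full control* the displayed motion is
the participant's own (weight $w = 1$); under *partial control* it is an
equal mixture of the participant's and a second actor's motion
($w = 0.5$). The display lags behaviour by a fixed latency (default 9
frames, about 300 ms at 30 fps). After each 20-s trial the participant
rates their sense of agency ("how much control did you feel?") and their
self-identification ("how much did the face resemble your own?"), both on
a 0–100 scale, in a 2 × 2 (face × control) within-participant design with
5 repetitions per condition and 20 participants.

The theoretical backbone is a two-mode account of how agency judgments
weight sensorimotor evidence:

* **Exploitation** — engaged when the face is recognized as one's own and
  a prior belief of control exists. Judgments are acutely sensitive to
  prediction errors: felt agency drops sharply with small losses of
  control, and movements are precise and stereotyped.
* **Exploration** — engaged when no belief of control exists (someone
  else's face). Judgments weight action–feedback regularities; felt agency
  rises gradually with observed contingency, and movements are larger,
  more frequent and more varied, because they are how evidence of control
  is gathered.

## The agency model

The package formalizes the two response regimes as four-parameter logistic
curves of *sensorimotor consistency* $c \in [0, 1]$ ($1$ = perfect
control):

$$\mathrm{rating}(c) = b + \frac{A}{1 + e^{-k (c - c_0)}}$$

with slope $k$, midpoint $c_0$, rise $A$ and baseline $b$
(`agency_curve_params()`). The exploitation curve is steep with a high
midpoint ($k = 14$, $c_0 = 0.80$, $A = 95$, $b = 2$); the exploration
curve is gentle with a low midpoint ($k = 5$, $c_0 = 0.50$, $A = 80$,
$b = 5$). At these defaults the curves cross exactly once below $c = 1$:
exploitation reads *lower* at imperfect control (it punishes small
prediction errors) but *higher* at perfect control (stronger confidence
under an intact belief of control). Both properties are asserted by the
test suite. The source curves are drawn, not quantified, in the original
account; the logistic family is this package's minimal parametrization
able to express "steep versus gentle with differing end confidence", and
all slope/midpoint values are package choices, not published estimates.

Consistency is operationalized from the objective control measure:
$c = \mathrm{clip}(1 - e_{\mathrm{norm}} - r_0)$, where
$e_{\mathrm{norm}}$ is the latency-compensated motion error normalized by
the combined motion magnitude of the driving and displayed signals, and
$r_0 = 0.18$ is a *residual discrepancy* representing the technical
imperfection of the display (latency jitter, reconstruction error) that
keeps even full control below perfect consistency. This residual matters:
with $c = 1$ under full control, the exploitation curve would overtake the
exploration curve and the self-face would receive *higher* agency ratings,
contrary to the phenomenon under study; the paradigm depends on full
control being imperfect, and $r_0$ places its operating point at
$c \approx 0.82$ (partial control lands near $c \approx 0.4$).

`fit_curves()` recovers the per-mode parameters from trial data by
bounded Levenberg–Marquardt least squares with five seeded multistarts per
mode, reporting non-convergence through a flag rather than an error. With
consistency spread over $[0, 1]$ (200 trials per mode, rating noise
SD 5), the generating slopes are recovered within ±20 % in ≥ 90 % of
seeded replicates. In the default experiment, consistency clusters at the
two operating points, so the absolute slopes are only weakly identified —
the slope *ordering* ($k_{\mathrm{exploit}} > k_{\mathrm{explore}}$) is
what the design can support, and it is reliably recovered.

## The synthetic-data generator

`generate_actor_motion()` emulates webcam-tracked facial-landmark motion
on a neutral mesh (default: a 64-landmark procedural topology; the
canonical 468-landmark face-mesh topology is available with a packaged
approximate region map). Coordinates are dimensionless, mirroring
landmark trackers that carry no metric calibration; the face spans
roughly $[-1, 1]$.

Motion is *episodic*: each channel — rigid head pose, blinks
(periocular), mouth gestures (perioral) — produces discrete action
episodes (raised-cosine bumps with a 1-s refractory gap) at Poisson rates,
on top of a small continuous postural wander of the head (AR(1) plus
low-frequency sinusoids) and white per-landmark tracking jitter
(SD 0.002). A *dominant-channel schedule* switches which channel currently
initiates actions (expected `switch_rate` switches/min; the dominant
channel's episode rate is boosted 2.5-fold, the others damped to 0.15),
and a physiological floor guarantees at least two episodes per channel per
trial (people blink and shift regardless of what they attend to).
Exploration (other-face) behaviour differs from exploitation (self-face)
behaviour in three coupled ways, matching the theory's action-policy
predictions: amplitudes × 1.6, episode rates × 2, and dominance switching
at 12 vs 5 per minute. Participants get lognormal multipliers on amplitude
and switch rate, a small jitter on their curve midpoints and a random
rating intercept, so between-participant variance is realistic for the
repeated-measures tests.

An earlier draft drove the facial channels with continuous oscillations;
because the diversity index z-normalizes each channel per trial, channels
without discrete events then contributed a stream of noise peaks and the
index degenerated into a noise-interleaving count. Real facial action is
episodic, and modelling it that way is also what makes the peak-switching
index meaningful; the episodic design (rates, refractory gap, floor) was
calibrated so that the generator satisfies its stated contract — the
study's effect directions are recoverable by the downstream pipeline in
at least 80 % of seeded replicates — and then frozen.

What the generator does *not* emulate: photorealistic rendering and the
deep-generative reconstruction artifacts of the real stimulus chain,
landmark-tracker bias differing between identities, gaze, speech, or any
within-trial belief dynamics (mode switching happens between trials
only). Passing tests therefore show that the analysis code measures what
it claims on data with known structure — not that the biological effects
would replicate.

## Kinematics and metrics

* **Rigid decomposition** — per-frame least-squares rigid alignment
  (Kabsch/orthogonal Procrustes, no scaling, reflection-guarded) of the
  quasi-rigid `head_rigid` landmark set against the neutral mesh.
  Head-motion magnitude is the frame-to-frame displacement of the
  transformed head centroid plus the mean arc length of head landmarks
  under the incremental rotation. Facial-muscle channels (periocular
  left/right, perioral) are measured after re-expressing each frame in
  the head-stabilized coordinate frame — whether the original analysis
  stabilized the head before measuring the muscle channels is not
  recoverable from the published text, so both modes are implemented and
  head-stabilized is the default. The `overall` channel is the mean
  per-landmark displacement with rigid motion left in.
* **Moving distance** — the path length (sum of per-frame magnitudes)
  over a trial, not net displacement, so larger and more frequent
  exploratory movement strictly increases it. No per-duration
  normalization is applied by default since all trials share one length.
* **Motion diversity** — each of {overall, head, periocular (pooled left
  + right), perioral} is smoothed (0.5-s centered moving average),
  z-normalized per trial (constant series map to zero), and searched for
  peaks with topographic prominence ≥ 1 z-unit and ≥ 0.3 s separation
  (conflicts keep the higher peak, ties the earlier). All peaks merge
  into one time-ordered sequence (time ties broken by the fixed channel
  order) and the index is the number of adjacent channel switches per
  minute. The exact parameters of the original index are in an
  unavailable supplement; these defaults assume sub-second facial actions
  with one dominant action at a time, and are all tunable.
* **Motion error** — driving and displayed trajectories are converted to
  displacement-from-neutral fields (identity-free, so self- and
  other-face trials are comparable), the display latency is estimated by
  a cross-correlation scan over 0–0.5 s and compensated, and the error is
  the mean over frames of the RMS landmark displacement difference. Under
  50/50 mixing this equals half the mean RMS difference between the two
  actors' fields — an identity the tests verify numerically.

## The statistical battery

The 2 × 2 repeated-measures ANOVA is computed from per-participant effect
contrasts: in the fully within two-level case each effect's $F$ (df 1,
$n - 1$) is exactly the square of the paired $t$ on its contrast, and
partial $\eta^2 = F/(F + n - 1)$. This closed form is implemented
directly so that equivalence tests against a brute-force sums-of-squares
decomposition and `stats::aov` hold to $10^{-10}$. Supporting functions
cover Bonferroni-corrected thresholds ($\alpha/m$), Cohen's $d_z$, the
signal-detection $d'$ with the $1/(2N)$ extreme-rate correction, a
repetition-trend check (per-cell least-squares slope against repetition,
then a one-sample $t$ of slopes per condition — a re-specification, since
the original repetition check's exact form is not stated), and power via
the noncentral $t$ distribution. The published power analysis (effect
size $d = 0.617$, one-tailed $\alpha = 0.05$, power 0.8, $n = 18$) is
reproduced by the *matched-pairs* noncentral-$t$ formulation
(df $= n - 1$, noncentrality $d\sqrt{n}$); the text calls the test
"independent", but an independent-groups design at that effect size needs
roughly 35 per group, so both designs are implemented and the paired one
is treated as what was actually computed.

## Numerical choices and degenerate inputs

Rigid alignment refuses collinear point sets (non-unique rotation);
incremental rotations with angles below $10^{-7}$ rad contribute no arc
term (the axis is numerically undefined there); zero-variance series
z-score to zero, return latency 0 with a warning in the cross-correlation
scan, and make the paired $t$ an error unless the samples are identical
(then $t = 0$, $p = 1$); a contrast that is identically zero reports
$F = 0$, while zero error variance around a non-zero mean reports
$F = \infty$ with a warning. All simulation randomness descends from one
master seed through a hash of stage and trial labels, so any single trial
is reproducible in isolation and trajectories are bitwise identical under
the same seed. Episode draws are made at unit scale before any amplitude
is applied, which keeps trajectories comparable across amplitude settings
and makes non-rigid path length exactly linear in the amplitude
multiplier — a property the tests exploit.

## Problem sizes

The test suite runs the full default study — 20 participants × 2 × 2
conditions × 5 repetitions of 20-s, 30-fps trials on the 64-landmark
mesh — across 50 seeded replicates for the effect-direction check, plus a
50-replicate curve-recovery study (400 trials each) and a
100,000-replicate Monte-Carlo power oracle; unit tests use 12–64-landmark
meshes and 1–4-s trials. These sizes keep a complete run of the battery
in the tens of minutes on a single core while leaving every replicate at
the study's own scale.

## Limitations

The generator's effect sizes are package choices: the synthetic agency
and identification effects are stronger than the published ones (the
published partial $\eta^2$ range from 0.2 to 0.8), so the pipeline's
qualitative directions — not its $F$ magnitudes — are the reproduction
target; exact statistics are only reproducible from the study's deposited
data, for which a schema-driven reader (`read_external_ratings()`) is
provided. The diversity index's published parameters are unknown, so
quantitative comparisons of switch rates to the original figures are not
meaningful. The mixing model is a plain convex combination; whether the
original latent-space mixing renormalizes amplitude is unstated, so a
renormalization flag exists but defaults to off.
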