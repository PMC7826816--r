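---
title: "Predicting imminent behavioral escalation from multimodal wearable streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting imminent behavioral escalation from multimodal wearable streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escalert)
library(dplyr)
```

## The problem

Children with autism spectrum disorder who present dangerous or disruptive
problem behavior often show *precursors* — milder, observable behaviors that
reliably precede an episode. If an automated system can flag, tens of seconds
ahead, that a precursor is imminent, a caregiver can withdraw a demand or
redirect the child before escalation. `escalert` implements such a pipeline
end to end: multimodal wearable streams are conditioned, fused on a common
movement timeline, labelled against therapist event logs, and fed to standard
classifiers, individually per child and pooled across children.

Five modalities are modelled, at the rates real hardware produces them:

| stream  | rate | content |
|---------|------|---------|
| motion garment | 15 Hz | 7 IMUs (accelerometer + magnetometer triplets): both forearms, both upper arms, three back positions |
| blood volume pulse | 64 Hz | wrist PPG |
| electrodermal activity | 4 Hz | skin conductance, microsiemens |
| wrist acceleration | 32 Hz | 3 axes, g |
| face/head tracking | 10 Hz | head roll/pitch/yaw plus discrete facial scores in {0, 0.5, 1} |

A sixth input is the behavioral event log: millisecond-stamped condition
switches (evocative *EO* vs reinforcing *S^R*), calm on/off marks, precursor
and problem-behavior events, recorded by a trained observer under an
IISCA-style functional-analysis protocol.

## Orientation and pose from the motion garment

Each IMU yields an orientation by tilt-compensated geometry, with no
gyroscope integration: roll and pitch from the gravity direction
(`roll = atan2(a_y, a_z)`, `pitch = atan2(-a_x, sqrt(a_y^2 + a_z^2))`, with
the accelerometer reading +1 g opposite gravity at rest), and yaw from the
magnetometer after de-rotating roll and pitch. The segment rotation is
`R = Rz(yaw) Ry(pitch) Rx(roll)`. This is exact for a quasi-static sensor
with roll and pitch inside (−π/2, π/2) and a magnetic field with a nonzero
horizontal component; during fast movement the gravity estimate is noisy,
which is a real limitation of accelerometer-only orientation and is
reproduced by the simulator.

Joint positions follow by forward kinematics over a tree rooted at the spine
base (x front, y left, z up): each joint contributes a homogeneous transform
`H = [R d; 0 1]` with `d` the measured link vector in mm, and the position of
joint *n* is the translation part of `H_1 ... H_n`. Two properties anchor the
tests: composition equals an independently coded matrix-product oracle, and
adjacent-joint distances equal link lengths for *every* pose.

```{r fk}
model <- default_body_model()
pose <- forward_kinematics(
  tibble::tibble(joint = model$joint, roll = 0, pitch = 0, yaw = 0), model
)
pose
```

## Signal conditioning

All filters are 4th-order Butterworth run forward-backward (zero phase),
because every feature is aligned against millisecond behavioral timestamps
and a causal filter's group delay would shift features relative to labels.
The wrist acceleration gets a 10 Hz low-pass; the blood volume pulse a
1–8 Hz band-pass before beat detection. The motion stream samples at 15 Hz,
whose Nyquist limit (7.5 Hz) is below the 10 Hz used for the faster
accelerometers, so its low-pass defaults to 6 Hz — still above the
frequencies of human limb motion. `lowpass_filter()` refuses cutoffs at or
above Nyquist rather than silently aliasing.

Corruption handling and imputation are deliberately asymmetric across
modalities, matching how the respective sensors fail:

* IMU rows are rarely corrupted (radio glitches; well under 1% of rows).
  `scrub_corrupted()` marks non-finite values and accelerations beyond the
  ±16 g full scale as missing; gaps of at most 2 samples are bridged
  linearly, longer gaps stay missing and their rows are excluded from the
  feature timeline.
* Face/head tracking drops out in bursts (about a quarter of the time, when
  the child looks down or away). Missing head rotations take the mean of the
  20 timestamp-closest available samples; missing facial scores take the
  mode of the 20 closest, ties resolved to the single nearest sample. "20
  closest" is interpreted bilaterally (either side in time); offline
  processing has no reason to restrict to past samples.

## Features and fusion

The fused vector has 32 features in the default configuration:

* 20 motion features: roll, pitch, yaw (degrees) and activity level for the
  left/right forearm, left/right upper arm, and torso. The torso aggregates
  the three back IMUs by the arithmetic mean of their angles; each segment's
  activity level uses its own accelerometer. Activity level is the mean
  acceleration magnitude over a trailing 1-s window,
  `AL = mean(sqrt(ax^2 + ay^2 + az^2))` — a printed variant dividing by a
  constant 7 instead of the sample count is available as a strict-mode
  toggle and only rescales the feature.
* heart rate (bpm) as `60 / mean(IBI)` over a trailing 10-s window of
  inter-beat intervals from detected systolic peaks;
* tonic level (SCL) and phasic response (SCR) of skin conductance, where SCL
  is a 0.05 Hz zero-phase low-pass and SCR the residual, so SCL + SCR
  reconstructs the signal exactly. Deconvolution-based phasic estimators are
  deliberately out of scope: the additive decomposition is reconstructible
  and sufficient for a rate-of-transients feature.
* the three wrist acceleration axes;
* 6 face/head features: head roll/pitch/yaw plus the happy, engaged and
  looking-away scores. The eyes-closed and mouth-open scores are available
  through the `extended` feature set; the default set keeps 32 columns with
  head rotations included, which reconciles the published feature count with
  the separate treatment of head rotations in the importance analysis.

Fusion takes the 15 Hz motion timeline as the basis: one row per motion
sample, every other modality contributing its timestamp-closest sample
(ties to the earlier sample). Values are carried verbatim — no interpolation
at the fusion stage — so every fused value is traceable to a source sample.

## Labels, models, evaluation

A row is labelled 1 when some precursor event lies within `W` seconds
*after* it (boundaries inclusive; default `W = 90` s). Rows during EO and
S^R are labelled by the time rule alone, and rows after the last precursor
keep label 0 — the simplest reading of the windowing rule; condition-based
masking and post-event exclusion are possible refinements we did not adopt
because the protocol gives no ground truth for them.

Seven classifier families run behind one interface: random forest
(100 trees), RBF support vector machine, k-nearest neighbours (k = 5),
decision tree, linear discriminant analysis, naive Bayes, and a
single-hidden-layer neural network (64 units). None of these
hyperparameters were tuned; they are the conventional defaults.
Individualized models are scored by stratified 5-fold cross-validation (an
80/20 stratified holdout with its confusion matrix is available as
`holdout_individual()`); group models by leave-one-subject-out validation.
Random-forest feature importances are impurity decreases normalized to sum
to 1, with modality importances as sums over member features.

One caveat worth stating plainly: random fold assignment on 15 Hz samples
places temporally adjacent (hence strongly correlated) rows in train and
test, which inflates individualized accuracies — for real early-warning
deployment a blocked or session-wise split would be more honest. We keep
random folds because they are the evaluation protocol this pipeline models,
and the group (leave-one-subject-out) numbers are immune to that artifact.

## The session protocol state machine

Sessions follow a multielement design in C,T,C,T,T order: control sessions
present only S^R; test sessions alternate EO and S^R. The evocative
condition may only begin after **90 s of continuous observed calm** within
S^R — any precursor, problem behavior, or calm-off mark resets the timer.
After a precursor in EO the therapist returns to S^R and the same gate
applies to the next EO. (The alternative literal reading — a countdown
running *inside* EO after a precursor — contradicts the described S^R
logic, so we adopted the reinforcement-first interpretation.) The state
machine (`fsm_step()`) validates recorded logs event by event;
`replay_event_log()` collects violations and reconstructs the latent
condition/calm timeline. Timers accrue continuously at event resolution
(ms); simulated clock ticks are provided at 1 s resolution via `fsm_tick()`.

## The synthetic cohort

No public recordings of this kind exist, so the package ships a seeded
generator that every pipeline stage is tested against. Its signal model is
invented — sinusoid-plus-noise limb orientations rendered through the exact
sensor model (`R^T g`, `R^T m` plus noise), a template-pulse PPG driven by an
instantaneous heart rate, tonic drift plus exponential-decay transients for
skin conductance, and categorical facial scores — but its *aggregate
statistics* are calibrated to the published feasibility numbers: per-session
durations around 12.1/11.4/10/10.7/10.1 min (≈54 min per visit), about 26
precursor episodes per visit clustered into EO-triggered cycles, a ~6:4
calm/pre-precursor class ratio at the 90-s window, 26.9% face/head dropout
(in bursts averaging 2 s), and 0.3% IMU row corruption.

Escalation is a latent intensity that is 0 outside the 90 s before each
precursor and inside it ramps from a jump of 0.35 at onset to 1 at the
event, driving motion amplitude (scaled ×2.5 at full intensity, full gain on
the dominant arm, 40% of the extra on the other side), heart rate (+25 bpm),
phasic EDA event rate (×5), head motion, and facial-score distributions.
The onset jump plus ramp is a deliberate design choice: a graded signature
keeps 30/60/90-s labels separable from each other (as observed in practice),
while anything earlier than 90 s is signal-free — which is exactly what
degrades a 120-s labeling window. Between-subject heterogeneity scales the
spread of physiological baselines, posture baselines, gains, facial
distributions, and dominant side; at `heterogeneity = 0` all subjects share
one profile and differ only through seeds.

What passing tests on this cohort do **not** show: robustness to real motion
artifacts in PPG, magnetometer disturbance indoors, sensor placement shift,
or behavioral idiosyncrasies beyond the modelled gains. The simulator only
exercises what the features can sense.

## Numerical and design choices

* Two-argument arctangents everywhere; yaw in (−π, π], roll/pitch valid in
  (−π/2, π/2). The orientation equations are implemented in the internally
  consistent form implied by the rotation matrix (the roll/pitch formulas
  follow the standard tilt derivation).
* Zero-phase filtering mean-centers low-passed signals before
  `filtfilt` and restores the mean, avoiding start-up transients at very low
  normalized cutoffs (the 0.05 Hz tonic filter at 4 Hz sampling is the
  critical case).
* Peak detection uses a refractory distance corresponding to 210 bpm and an
  adaptive height threshold; windows with fewer than two beats yield a
  missing heart rate, bridged by nearest-value interpolation before fusion.
* Oversampling duplicates minority rows with replacement under an explicit
  seed; it is used only for the window-sensitivity comparison, since the
  natural ~6:4 ratio needs no rebalancing.
* All stochastic steps (generation, fold assignment, bagging, resampling)
  take explicit integer seeds; identical seeds give bit-identical results.

## Problem sizes used by tests and the acceptance script

Full-length visits (~54 min) are used wherever only generation and labeling
are involved (protocol validity, class ratio, dropout rate). Model-fitting
analyses run on visits scaled to 25% duration with the cycle structure
unchanged (~12,000 fused rows per subject, three-subject cohorts), which
keeps the full suite within a few minutes on one CPU while leaving every
qualitative contrast intact. The command-line smoke tests use still shorter
visits.

## Known limitations

* Accelerometer-only orientation degrades under sustained acceleration;
  no complementary/Kalman fusion is attempted (the hardware's gyroscopes are
  unused by the published equations).
* Arithmetic averaging of back-IMU yaw angles is inappropriate near ±180°;
  baseline postures keep torso yaw far from the wrap.
* Labels inherit observer reaction time in real logs; the simulator has no
  annotation latency model.
* No HRV, frequency-domain, or gesture-classification features; no skin
  temperature.
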