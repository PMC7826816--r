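# escalert

Predicting *imminent precursors* of problem behavior in children with autism
spectrum disorder from multimodal wearable recordings. The package is aimed
at researchers in behavioral sensing and applied behavior analysis who need
a complete, reproducible reference pipeline: from raw sensor streams and
therapist event logs to windowed labels, trained classifiers, and
importance/sensitivity analyses — plus a seeded synthetic cohort simulator,
since clinical recordings of this kind are not publicly distributable.

## What it computes

**Inputs.** Five timestamped streams per session — a 7-IMU upper-body motion
garment (15 Hz accelerometer/magnetometer per IMU), blood volume pulse
(64 Hz), electrodermal activity (4 Hz), wrist acceleration (32 Hz), and
face/head tracking (10 Hz) — and a millisecond-stamped behavioral event log
from an IISCA-style session protocol (evocative *EO* vs reinforcing *S^R*
conditions, calm marks, precursor events).

**Kinematics.** Per-IMU tilt-compensated orientation from gravity and the
magnetic field,

    roll  = atan2(a_y, a_z)
    pitch = atan2(-a_x, sqrt(a_y² + a_z²))
    yaw   = atan2(m_z sin(roll) − m_y cos(roll),
                  m_x cos(pitch) + m_y sin(pitch) sin(roll) + m_z sin(pitch) cos(roll))

with segment rotation `R = Rz(yaw) Ry(pitch) Rx(roll)`, and upper-body joint
positions by composing homogeneous transforms `H = [R d; 0 1]` along the
joint tree (`d` = measured link vectors, mm).

**Features.** 32 per instant on the 15 Hz movement timeline: per-segment
roll/pitch/yaw and activity level `AL = mean ‖a‖` (5 segments × 4), heart
rate `HR = 60 / mean(IBI)` from detected pulse peaks, tonic/phasic skin
conductance (`SCL` = 0.05 Hz zero-phase low-pass, `SCR` = residual, so
`SCL + SCR` reconstructs the input), the three wrist acceleration axes, and
head rotations plus facial scores — each non-motion modality fused by its
timestamp-closest sample.

**Labels and models.** A row is labelled 1 iff a precursor occurs within
`W = 90` s after it. Seven classifier families (random forest, SVM, kNN,
decision tree, LDA, naive Bayes, neural network) are evaluated with
stratified 5-fold cross-validation per subject and leave-one-subject-out
across subjects, with impurity-based feature/modality importances and a
window-sensitivity analysis over `W ∈ {30, 60, 90, 120}` s (minority class
oversampled to 1:1).

**Protocol.** The session state machine enforces C,T,C,T,T session order,
S^R-only control sessions, and the rule that an EO presentation requires at
least 90 s of *continuous* observed calm; it validates real or simulated
logs and reconstructs the latent condition/calm timeline.

## Worked example

```r
library(escalert)

# three synthetic subjects, heterogeneous profiles, quarter-length visits
cohort   <- generate_cohort(3, heterogeneity = 1, seed = 11,
  base_profile = subject_profile(policy = protocol_policy(duration_scale = 0.25)))
datasets <- cohort_datasets(cohort, window_s = 90)

crossval_individual(datasets$S01, "rf", seed = 1)
#> <escalert_cv> rf, 5-fold: accuracy 0.9930 (folds 0.991 0.990 0.998 0.994 0.992)

loso_group(datasets, "rf", seed = 1) |> tidy()
#> # A tibble: 3 × 4
#>   subject_id accuracy     n flagged
#>   <chr>         <dbl> <int> <lgl>
#> 1 S01           0.917 12198 FALSE
#> 2 S02           0.750 12198 FALSE
#> 3 S03           0.694 12198 FALSE

feature_importance(datasets$S01, seed = 1)$per_modality
#> # A tibble: 5 × 2
#>   modality           importance
#>   <chr>                   <dbl>
#> 1 physiology             0.387
#> 2 head_rotations         0.254
#> 3 body_motion            0.198
#> 4 facial_expressions     0.146
#> 5 wrist_acceleration     0.0167
```

Individualized 5-fold accuracy is ~0.99 while the same algorithm trained on
the *other* subjects scores 0.69–0.92 on the held-out child: escalation
signatures are individual, so a group model transfers poorly. Importances
sum to 1 over the 32 features; modality values are sums over member
features.

A thin command-line shim is installed at `inst/cli/escalert`:

```sh
Rscript inst/cli/escalert simulate --out data/cohort --cohort 3 --seed 7
Rscript inst/cli/escalert validate-log --log data/cohort/S01/S01_s2_test_events.tsv
Rscript inst/cli/escalert evaluate --dir data/cohort --algo rf --mode group --seed 1
```

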