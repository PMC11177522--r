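---
title: "Mapping spastic muscle activity with HD-sEMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spastic muscle activity with HD-sEMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spasmap` analyses high-density surface EMG from an 8 × 8 electrode grid
(12 mm pitch, monopolar, 2 kHz) placed over the biceps brachii, comparing
the *intensity* and *spatial distribution* of muscle activity between
passive isokinetic stretches (10/60/120/180 °/s) and isometric contractions
(20/50/80 %MVC) in spastic and healthy subjects. This vignette documents the
model behind each processing stage, the tunable parameters, the synthetic
cohort the package validates itself on, and the design decisions that were
genuinely open.

## The analysis chain

**Filtering.** Each channel passes a 50 Hz notch (2nd-order RBJ biquad,
Q = 30) and a 6th-order Butterworth band-pass, 20–500 Hz. Both are applied
zero-phase (forward–backward) by default: the analysis is offline, and a
causal pass would delay the EMG envelope relative to the joint-angle/force
trace used for epoch segmentation. Causal mode is available
(`filter_settings(zero_phase = FALSE)`). Only the 50 Hz fundamental is
notched; harmonics can be added by filtering again with a different centre
frequency. The cascade's measured contract — at least 26 dB attenuation at
50 Hz, under 0.5 dB ripple at 150 Hz, DC below 1e-3 — is asserted in the
test suite via `filter_response()`.

**Bad channels.** Poor electrode–skin contact is detected automatically: a
channel is bad if its RMS falls below `flat_eps` (1e-4 mV; flatlined) or if
its log-RMS deviates from the mean of its 4-neighbours by more than
`z_thresh` (3) robust z-scores. The *spatial residual* is used rather than
the raw log-RMS because genuine focal activation makes whole neighbourhoods
of channels into amplitude outliers, whereas a contact artifact is a
single-electrode event whose log residual is large (a 10× amplitude change
is 2.3 natural-log units). Channels are flagged one at a time, worst first,
and removed from the neighbour means before re-testing, so one gross
outlier cannot drag its neighbours over the threshold. The residual scale
is floored at 0.15 log units: on very clean recordings the empirical
roughness approaches the RMS sampling error, and without the floor any
activation peak would look like an outlier; contact artifacts sit far above
the floor, so no sensitivity is lost.

Flagged channels are replaced sample-wise by the mean of their valid
4-neighbours, iterating outside-in until every channel is filled
("adjacent channels" is read conservatively as the 4-neighbourhood). The
average is rescaled to the neighbours' mean RMS: to the extent that
neighbour signals are uncorrelated, plain averaging attenuates amplitude
(by half for four independent channels), which would stamp a hole into the
activation map exactly where a map peak might be. For strongly correlated
real channels the rescale factor is close to 1. Interpolated channels stay
excluded from the effective-channel count used for trial selection.

**Epochs.** The stretch of the biceps is the elbow *extension*: the epoch
runs from where the smoothed angular velocity exceeds half the nominal task
velocity until the extension stops. Velocity is estimated by a central
difference over a 50 ms half-window plus a 50 ms moving average —
sample-wise differentiation of a noisy angle trace is useless at these
velocities. For active trials the "stable" 3 s epoch is operationalised as
the window minimising the coefficient of variation of the force trace
(0.1 s scan step, earliest window on ties). Of the three trials per
condition, the epoch recorded with the most effective channels is analysed
(lowest trial index on ties).

**Activation maps.** Per channel, the RMS of non-overlapping 200 ms windows
is averaged over the M full windows; a trailing partial window is
discarded rather than zero-padded so the window statistics stay unbiased
(at 180 °/s the epoch is ~0.5 s, M = 2, and padding bias would be worst
exactly there). The normalisation constant `RMS_max` is a **single scalar
per subject**: the maximum single-window RMS over all windows, channels and
the three MVC trials. The defining equation subscripts the numerator with
(i, j) but not `RMS_max`, and a per-channel normalisation would erase the
spatial structure the maps exist to show; per-channel mode can still be
mimicked by building maps from per-channel constants if wanted. Mean map
intensity is the arithmetic mean of the 64 original values; the 71 × 71
cubic-spline upsampling (`upsample_for_display()`) is strictly for figures
and feeds no statistic.

**Baseline.** The 10 °/s stretch does not elicit a reflex and serves as the
subject's resting map. Under the default policy (`baseline_scope =
"cog_all"`) it is subtracted (element-wise, clamped at zero) from both the
passive and the active maps before CoG extraction *and* segmentation, so
that both spatial statistics see the same maps; `cog_passive_only` and
`none` are available. Reported mean intensities are always unsubtracted.

**Segmentation.** The h-dome transform `D_h(AM) = AM − R(AM − h | AM)`
(grayscale reconstruction by dilation, 8 × 8 grid, 4- or 8-connectivity)
extracts local-maximum structures of height at least h. The dome image is
binarised above `dome_floor` (1e-6, guarding numerically-zero plateaus),
cleaned with a binary opening (2 × 2 square; 3 × 3 annihilates realistic
clusters on an 8 × 8 grid), and the connected component containing the map
maximum becomes the *relevant channels*. Ties between equal-peak clusters
go to the larger summed nRMS, then the smaller row-major peak index. If the
opening empties the dome image the unopened binarisation is used with a
warning. `h` is specified as a fraction of the map's dynamic range so it
survives normalisation differences; the default is **0.45**. The value is
dictated by grid geometry: activation blobs on this muscle have an SD of
roughly 1.2–1.3 electrode pitches, so the drop from a blob peak to its
neighbouring electrode is already ~20–25 % of the range — an h below that
yields single-electrode "clusters" whose overlap degrees are degenerate
(0 or 100 %), incompatible with cluster areas of several channels.
Sensitivity: at h = 0.30 clusters shrink by roughly the boundary ring and
within-task overlaps drop a few points; at h = 0.60 neighbouring structures
begin to merge. A flat map is a single regional-maximum plateau, so its
dome is h everywhere by the defining formula; segmentation treats
zero-range maps as clusterless before the transform is ever applied.

**Overlap degrees.** `100·|A∩B| / max(|A|,|B|)`, defined as 0 with a
warning when both masks are empty. "Within-task" is the mean over the three
velocity pairs (60/120/180) or the three level pairs (20/50/80);
"between-tasks" compares the clusters of the velocity-averaged and
level-averaged maps.

**Statistics.** The group layer replicates the study design literally:
mixed two-way repeated-measures ANOVA (between factor group, within factor
task; group tested against subjects-within-groups, task and interaction
against the task × subject error), post hoc Student (pooled-variance)
independent t-tests per task, one-way repeated-measures ANOVA within each
group, and paired t-tests on CoG coordinates. No sphericity correction and
no multiple-comparison correction are applied by default, matching the
original analysis; Greenhouse–Geisser and Welch variants are config
options. The one-way ANOVA within a group is read as repeated-measures
(same subjects across tasks); a between-trials reading would discard the
pairing the protocol provides. Degenerate inputs (zero error variance,
constant differences) warn and return NaN/err rather than fabricating
p-values. The decompositions are verified against `stats::aov` with
`Error()` strata to 1e-10 in the tests.

## The synthetic cohort

Clinical HD-sEMG recordings of this population are not publicly available,
so the package validates itself on a generative model
(`simulate_cohort()`). Each subject is a `subject_model`:

* **Spatial profiles.** Gain fields on the grid: a constant floor
  (broad monopolar pick-up) plus Gaussian blobs. Healthy voluntary
  activation has two blobs (SD 1.2 pitch) split across the innervation
  zone; spastic voluntary activation has a single blob (SD 1.3) placed
  slightly lateral and proximal; the spastic reflex profile is a broad
  central component (SD 2.3) plus a steep distal focus (SD 1.05). The
  two-component reflex profile is not cosmetic: the reported combination of
  a near-central passive CoG with a distal, largely non-overlapping reflex
  cluster implies diffuse background activity plus a focal source — a
  single blob cannot produce both.
* **Signals.** Per channel: `amplitude(t) × carrier(t)` + 50 Hz line
  (random phase, amplitude ~0.03 mV) + white sensor noise (SD 0.002 mV).
  The carrier is unit-variance band-limited (20–450 Hz) Gaussian noise,
  synthesised in the frequency domain, independent per channel; the band
  sits inside the pipeline's passband so preprocessing does not bias
  amplitude calibration. The amplitude envelope is the resting tone plus
  the task drive (amplitude-additive: task activity recruits motor units
  coherently with the background drive, and the resting map then subtracts
  out of task maps exactly).
* **Tasks.** Passive trials ramp the angle 90→180° at the task velocity
  with a reflex plateau (spastic, ≥60 °/s) during extension; the return
  phase is truncated since only the first extension is analysed. Active
  trials hold `level × MVC` force for 7 s with 2 % multiplicative force
  noise; the EMG envelope is `level^p` with p = 1.25 (healthy) and 0.55
  (spastic) — the values the task-intensity table fixes, and the spastic
  exponent below 1 encodes the inefficient submaximal recruitment after
  stroke. MVC trials run 5 s at envelope 1.
* **Variability.** Between subjects: blob centres jitter with SD 0.35
  pitch, amplitudes lognormally with CV 0.3 (reflex gains CV 0.22, floors
  CV 0.25). Between trials: activation centres wander with SD 0.12 pitch —
  without this, within-task overlaps would sit near 100 % rather than the
  low 80s real maps show. Each subject has 0–2 bad channels (flatline or
  10× noise).

The defaults were calibrated **once** so that the full pipeline, run on the
default cohort (14 spastic, 10 healthy), lands on the study-scale outputs
(task-intensity table, CoG coordinates, overlap degrees, and the
significance pattern), and then frozen; `scripts/acceptance.R` re-derives
those outputs from scratch at any seed. Raw amplitudes in mV are free
parameters (published maps are normalised); only ratios matter.

What the generator does **not** emulate: spatial correlation between
channels (each carrier is independent, making per-channel noise worst-case
and interpolation a harder test than on real data); motor-unit discreteness
and firing statistics (no decomposition-level realism); fatigue and
history effects across trials; innervation-zone shifts with joint angle;
and any longitudinal structure. Passing the suite therefore shows the
*pipeline* recovers the statistical structure it is given under realistic
noise — it does not certify the generator as a substitute for clinical
recordings.

## Numerical and scale choices

Test and validation runs use desk-scale sizes chosen to keep the whole
suite in the tens of minutes on one CPU: the acceptance cohort is the full
study-sized 14 + 10 (about 3–4 minutes end-to-end), unit tests use 1–4
subjects or single trials, oracle cross-checks use 200 random 8 × 8 maps
and 10–15 random small ANOVA designs, and the type-I calibration uses 2,000
null replicates. Reconstruction runs to its exact fixed point (no iteration
cap is needed on an 8 × 8 grid); all tie-breaks (trial selection, CV
windows, cluster peaks) are deterministic and documented above; epochs are
half-open sample ranges; and every random quantity flows from a single
cohort seed through per-subject seeds, so reruns are bit-identical.

## Known limitations

* The segmentation depends on h and the structuring element; both are
  config-exposed and their defaults are justified above, but on real data
  they deserve a sensitivity pass (the pipeline reports cluster sizes,
  which is the first thing to inspect).
* The bad-channel detector assumes spatially smooth activation; a genuine
  single-channel physiological hotspot (rare at 12 mm pitch) would be
  interpolated away.
* The CoG is a first-moment summary: bimodal healthy maps average their two
  lobes, which is faithful to the method but worth remembering when
  interpreting i/j shifts.
* Student t-tests and unadjusted post hocs replicate the original
  statistical design; for new analyses the Welch and Holm options exist and
  probably should be used.
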