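# spasmap

High-density surface EMG (HD-sEMG) activation mapping of the spastic biceps
brachii.

After a stroke, spasticity shows up as a velocity-dependent, involuntary
muscle response to passive stretch, while voluntary contraction is impaired.
`spasmap` implements an analysis pipeline for 64-channel electrode-grid EMG
(8 × 8, 12 mm inter-electrode distance, monopolar, 2 kHz) that quantifies
*where* on the muscle this activity lives and how the spatial patterns of
passive stretch and active contraction relate. It is aimed at
neurophysiology and rehabilitation researchers working with HD-sEMG grids.

## What it computes

For each subject and task (passive isokinetic stretch at 10/60/120/180 °/s;
isometric contraction at 20/50/80 %MVC; three MVC trials):

1. **Preprocessing** — 50 Hz notch + 6th-order Butterworth band-pass
   (20–500 Hz), automated bad-channel detection and grid interpolation,
   task-epoch extraction (first extension phase from the joint-angle trace;
   most stable 3 s of the force trace) and best-of-three trial selection.
2. **nRMS activation maps** — per channel, the mean RMS over 200 ms
   non-overlapping windows,

   `RMS = (1/M) * sum_m sqrt( (1/N) * sum_n u²(n) )`,

   normalised by the subject's maximal single-window MVC RMS:
   `AM[i,j] = nRMS[i,j] = RMS[i,j] / RMS_max`. Rows `i` run lateral→medial,
   columns `j` proximal→distal.
3. **Spatial statistics** — the activation centre of gravity
   `CoG = Σ AM[i,j]·(i,j) / Σ AM[i,j]` on baseline-subtracted maps (the
   10 °/s map is the resting baseline); h-dome grayscale-reconstruction
   segmentation plus morphological opening to isolate the *relevant
   channels* (the cluster holding the map maximum); and overlap degrees
   `100·|A∩B| / max(|A|,|B|)` within a task family and between the averaged
   passive and active maps.
4. **Group statistics** — mixed two-way repeated-measures ANOVA
   (group × task), post hoc independent t-tests per task, one-way
   repeated-measures ANOVA within group, and paired t-tests on CoG
   coordinates.

Because raw clinical recordings of this kind are not publicly deposited,
the package ships a calibrated synthetic-cohort generator
(`simulate_cohort()`, `make_subject()`, `simulate_trial()`) that emulates
the key phenomena: velocity-dependent distally-focused reflex activation
and proximal-lateral voluntary activation in spastic subjects, a two-peak
(innervation-zone split) voluntary pattern in healthy subjects, 50 Hz line
interference, a 20–450 Hz EMG carrier, and occasional bad channels. The
generator's defaults are calibrated so that the full pipeline reproduces
the group-level values reported for the real cohort; see the methods
vignette (`vignettes/activation-mapping.Rmd`) for the model and its
limitations.

## Worked example

Simulate a small cohort and run the full pipeline:

```r
library(spasmap)
res <- run_pipeline(simulate = list(n_spastic = 4, n_healthy = 3, seed = 42))
print(res)
#> <cohort_result> 7 subjects (4 spastic, 3 healthy)
#> overlap summary (%):
#>                category     mean        sd
#>  spastic within passive 83.33333 11.111111
#>   healthy within active 94.44444  5.555556
#>   spastic within active 75.00000  5.555556
#>  spastic between tasks  0.00000  0.000000
```

The overlap summary says that, for these synthetic subjects, the segmented
activation area is highly repeatable across stretch velocities (83%) and
contraction levels (94% / 75%), while the spastic passive and active areas
barely share any channels — the spatial signature of interest.

```r
subset(res$t_cog, select = c(comparison, t, df, p))
#>                                 comparison     t df      p
#>           active CoG i: spastic vs healthy -3.53  5 0.0168
#>           active CoG j: spastic vs healthy -2.06  5 0.0944
#>  spastic CoG i: passive vs active (paired)  1.29  3 0.2867
#>  spastic CoG j: passive vs active (paired)  5.10  3 0.0146
```

The spastic voluntary activation centre is significantly more lateral
(smaller CoG i, p = 0.017), and within the spastic group the stretch
response sits significantly more distal than the voluntary centre (paired
CoG j, p = 0.015) — even in this deliberately small cohort.

Per-subject tables (`res$intensity`, `res$cog`, `res$overlap`) and the
ANOVA/t-test tables (`res$anova`, `res$oneway`, `res$t_intensity`,
`res$t_cog`) are plain data frames; `export_results(res, "out/")` writes
them as CSV plus a JSON summary. A thin command-line wrapper is installed
at `inst/scripts/spasmap.R`:

```sh
Rscript inst/scripts/spasmap.R simulate --out data/ --n-spastic 2 --n-healthy 2 --seed 7
Rscript inst/scripts/spasmap.R analyze --in data/ --out results/
```

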