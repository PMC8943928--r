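# adlkin

Kinematic analysis of activities-of-daily-living (ADL) performance from
wrist-worn smartwatch accelerometry in older adults with and without
frailty.

## The problem

Frailty screening with the adapted Fried phenotype (five criteria:
unintentional weight loss, exhaustion, low physical activity, low grip
strength, slow walking speed; 0 positives = robust **R**, 1–2 =
pre-frail **P**, ≥3 = frail **F**) predicts loss of independence in
daily living, but ADL performance itself is usually assessed by
questionnaires or stopwatch times. This package implements a
sensor-based alternative: 100 Hz tri-axial wrist acceleration recorded
during two natural-paced manual ADL — preparing a cup of tea (**TEA**,
with a standardized 60 s boiling wait) and replanting a plant
(**GARDEN**) — is reduced to nine kinematic parameters that capture
*how* the hand moves rather than how long the task takes:

| group | parameters |
|---|---|
| activity | TD (trial duration, s), RA (fraction of time with \|a\| > 0.2 m/s²) |
| agility | STD (SD of acceleration-peak heights, m/s²) |
| smoothness | PPS (peaks per second, 1/s), RATIO (share of peaks with prominence ≥ 0.2 m/s²) |
| energy | SUM (Σa²/TD, m²/s⁵), APS (Σa/TD, m/s³) |
| intensity | MPA (mean peak height, m/s²), MAX95 (95th percentile of peak heights, m/s²) |

The preprocessing chain is: Euclidean magnitude → constant gravity
subtraction with rectification (|a − 9.81|) → 420 ms local-regression
(loess-type, tricube, degree 2) smoothing. The inferential stage runs
one-way ANOVAs with Tukey post hoc tests and partial η², a permutation
multivariate group test, inter-task Pearson correlations, and
forward-stepwise regression of the 0–5 frailty score (entry p ≤ 0.05,
removal p ≥ 0.10, VIF limit 5).

Because raw recordings of such cohorts are not publicly deposited, the
package ships a calibrated burst–pause signal generator
(`simulate_recording()`, `simulate_cohort()`) with known ground truth;
every stage is tested against it and against brute-force oracles. See
the methods vignette (`vignettes/adl-kinematics.Rmd`) for the model and
its assumptions.

## Worked example

```r
library(adlkin)

cfg <- default_sim_config(seed = 1)
rec <- simulate_recording(cfg, group = "R", task = "GARDEN",
                          participant_id = "P01")
prof <- extract_profile(preprocess(rec$recording))
round(unlist(prof[kinematic_parameters()]), 3)
#>      TD      RA     STD     PPS   RATIO     SUM     APS     MPA   MAX95
#>  73.220   0.720   0.920   2.376   0.167 156.158  88.293   0.708   2.616
```

A robust participant gardening for 73 s spends ~72% of the trial in
motion, produces ~2.4 acceleration peaks per second with mean peak
height ≈ 0.7 m/s² and a maximum near 2.6 m/s², and about a sixth of
those peaks are prominent distinct movements (the rest are tremor-scale
wiggles). Running the full workflow over the reference cohort
composition (8 R / 13 P / 6 F):

```sh
Rscript analysis/01_simulate_cohort.R    # recordings + manifest
Rscript analysis/02_extract_features.R   # results/features.csv
Rscript analysis/03_group_statistics.R   # ANOVAs, correlations, permutation test
Rscript analysis/04_regression_models.R  # stepwise frailty-score models
```

prints, among other things:

```
Permutation multivariate group test: statistic 89.6, p = 0.0002
 GARDEN       STD 23.468796 2.249146e-06 0.6616744
 GARDEN       MPA 20.361395 6.758466e-06 0.6291878
...
== Scope: avg ==
<regression_model> fried_score ~ STD_avg
  R2 = 0.452 (adj 0.430), model p = 0.0001, n = 27
  STD_avg      beta_std = -0.672  VIF = 1.00
```

i.e. the variability of acceleration-peak magnitudes (agility, STD)
separates the frailty groups — frailer participants move more
monotonously — while trial duration does not; the task-average
regression retains STD alone with a negative standardized beta, and
agility/intensity measures correlate between the two tasks (STD
r = 0.67) while TD does not (r = 0.13). This is the qualitative pattern
the pipeline is designed to detect.

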