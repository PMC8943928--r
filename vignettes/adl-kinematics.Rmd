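---
title: "Kinematic analysis of daily-living tasks from wrist accelerometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic analysis of daily-living tasks from wrist accelerometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlkin)
```

## The measurement problem

Frailty in older adults is usually screened with the five-criterion Fried
phenotype (unintentional weight loss, exhaustion, low physical activity,
low grip strength, slow walking speed; 0 positives = robust R, 1–2 =
pre-frail P, ≥3 = frail F). The phenotype predicts loss of independence in
activities of daily living (ADL), yet ADL performance itself is mostly
assessed by questionnaires or task times. A wrist-worn smartwatch recording
tri-axial acceleration at 100 Hz during natural-paced ADL — preparing a cup
of tea (TEA, with a standardized 60 s water-boiling wait) and replanting a
plant (GARDEN) — offers an objective alternative: the hypothesis is that
*how* the hand moves (smoothness, agility, intensity), rather than how
long the task takes, separates frailty levels.

`adlkin` implements that analysis end to end: signal preprocessing, nine
kinematic parameters, frailty scoring, and the group-comparison and
regression statistics — plus a synthetic-signal generator that emulates
the cohort structure so every stage is testable without access to raw
recordings.

## Preprocessing

The tri-axial series is reduced to a scalar magnitude in three steps:

1. **Euclidean magnitude** $a_i = \lVert (a_x, a_y, a_z)_i \rVert_2$.
   A resting sensor reads $\approx g = 9.81\,\mathrm{m/s^2}$ regardless of
   orientation.
2. **Constant gravity subtraction with rectification**,
   $a_i \mapsto |a_i - g|$. Subtracting a constant rather than an
   orientation estimate is deliberate: it requires no sensor fusion, and
   its known failure mode (underestimation of low horizontal
   accelerations) is part of what the simulation exercises through
   orientation wobble. Rectification precedes smoothing so no negative
   magnitudes enter the local regression.
3. **Local-regression smoothing** over a 420 ms window: locally weighted
   polynomial regression of degree 2 with tricube weights, span =
   window × sample rate rounded up to an odd count (43 samples at
   100 Hz), windows centred and truncated (not reflected) at the series
   edges. The tricube bandwidth is the half-width + 1, so every sample in
   a window keeps positive weight. Interior samples share one design
   matrix, so the smoother reduces to a convolution kernel; edge samples
   get individual weighted least-squares fits. Residual negatives after
   smoothing are clipped at zero. The published analysis names only "a
   420 ms local regression"; degree, weights, edge policy and the
   clipping rule are this package's documented choices, validated in the
   tests against an independently coded per-window WLS oracle.

## The nine kinematic parameters

All parameters are computed from one preprocessed magnitude signal and a
single peak-detection pass. Peaks are **all** strict local maxima (a
plateau counts once, at its first sample; edges never count), with no
minimum height: the peak-ratio denominator is meant to include noise
peaks. Prominence is topographic: height above the higher of the two
lowest points separating the peak from higher terrain or the series edge.

| Group | Parameter | Definition | Unit |
|---|---|---|---|
| activity | TD | samples / sample rate | s |
| activity | RA | fraction of samples with $a > 0.2$ (strict) | – |
| agility | STD | sample SD (n−1) of peak heights | m/s² |
| smoothness | PPS | peak count / TD | 1/s |
| smoothness | RATIO | peaks with prominence ≥ 0.2 (inclusive) / all peaks | – |
| energy | SUM | $\sum a_i^2$ / TD | m²/s⁵ |
| energy | APS | $\sum a_i$ / TD | m/s³ |
| intensity | MPA | mean peak height | m/s² |
| intensity | MAX95 | 95th percentile of peak heights, type-7 interpolation | m/s² |

Two conventions deserve emphasis. First, SUM and APS are **per-second
sums** ($\Sigma/TD$, i.e. per-sample means × sample rate): this is the
convention that reproduces both the printed units (m²/s⁵, m/s³) and the
numeric scale (≈20 m²/s⁵ and ≈20 m/s³) of the published cohort tables;
a per-sample mean would be two orders of magnitude smaller. Second, the
95th percentile interpolates linearly at position $(n-1)p$ (R's default
type 7). Undefined values — STD with fewer than two peaks, peak-based
measures with none — are reported as `NA`, never as zero.

## Frailty scoring

`fried_score()` counts positive criteria (all five must be adjudicated; no
imputation), and `categorize_frailty()` applies 0 → R, 1–2 → P, 3–5 → F.
Applying the rule to the reference score distribution (8×0, 6×1, 7×2,
3×3, 3×4) reproduces the 8/13/6 group sizes. The clinical
operationalization of each criterion (grip-strength cutoffs and the like)
is out of scope; the pipeline consumes adjudicated booleans.

## The synthetic-signal generator

No public recordings exist for this kind of cohort, so the generator is a
first-class module with ground truth, not a test fixture. Each recording
is built in the magnitude domain and then distributed over axes:

* **Trial skeleton.** Trial duration ~ N(mean, sd) per cell; a target
  pause fraction is realized as a fixed mid-trial pause for TEA (60 s
  from second 40, the boiling wait) plus randomly placed pauses of mean
  length ≈ 6 s.
* **Movement bursts.** A Poisson number of bursts per second of active
  time, each a Gaussian bell (sd = duration/4) with a log-normal peak
  amplitude, placed inside active intervals with a margin so pauses stay
  clean. The bell shape matches what loess smoothing makes of real
  reach–grasp bursts; nothing generative is claimed beyond that.
* **Sustained plateau.** Active phases additionally carry a low sustained
  level (ramped on/off with 1 s raised-cosine tapers): manual ADL keeps
  the wrist in continuous low-intensity motion between distinct actions.
  Without it, no isolated-burst configuration can simultaneously hit the
  published relative-activity (≈0.4–0.75) and energy (≈20 m/s³) levels.
* **Postural tremor.** Magnitude-domain white noise (default
  0.18 m/s²) throughout the trial, giving pauses the small peaks
  (≈0.15 m/s²) that the published mean-peak values imply.
* **Orientation.** The magnitude is carried by a unit orientation field:
  a gravity axis with slow 0.1 Hz sinusoidal wobble, perturbed in each
  burst's random direction, plus per-axis sensor noise (0.05 m/s²). The
  Euclidean magnitude of the noiseless signal is therefore exactly
  gravity + envelope, which makes ground-truth tests sharp.
* **Participant traits.** A participant-level amplitude factor (12% of
  the log-amplitude variance) and pause-proneness are shared between the
  two tasks of one participant. This yields the positive inter-task
  correlations of agility/intensity measures (r ≈ 0.4–0.7) seen in real
  cohorts while leaving trial duration essentially uncorrelated.

Determinism: every random quantity derives from the configuration seed
and the participant/task identifiers, so identical configurations give
bit-identical cohorts and the generator never touches the caller's RNG
stream.

### Calibration and what it does not claim

`default_sim_config()` encodes six group×task cells calibrated so that
cohort means of TD, RA and MPA at n = 30 recordings per cell fall within
±20% of the published group×task means, with the published orderings
(GARDEN more intense than TEA; robust > pre-frail > frail peak
amplitudes within GARDEN; frail TEA peaks rarely above ≈1.2 m/s² while
robust TEA peaks reach ≈4 m/s²). Frailer cells use slightly denser,
lower-amplitude bursts — more, smaller movement segments — which also
reproduces the published direction of the peaks-per-second contrast.

The calibration is by construction approximate and deliberately binds
only TD, RA and MPA. Known deviations: the GARDEN energy measures (SUM,
APS) and MAX95 run higher than the published cells (the sustained-plateau
plus burst model pays for matching RA and MPA with extra signal energy);
RATIO runs lower everywhere (tremor peaks dilute the prominent-peak
share); and the simulated group effect sizes on GARDEN agility/intensity
(η²p ≈ 0.6) are stronger than the published borderline effects
(η²p ≈ 0.2–0.3), which makes the end-to-end recovery tests stable across
seeds rather than marginal. Passing tests on this generator demonstrate
that the pipeline recovers structure *of this kind* from signals *with
these properties*; they cannot certify behaviour on real smartwatch data,
vendor-specific artifacts, or non-stationary sensor placement.

## Statistics

* **Per-parameter group comparisons**: classical one-way ANOVA with
  partial eta squared $\eta_p^2 = SS_b/(SS_b+SS_w)$, Tukey HSD post hoc
  tests on the studentized-range distribution, and pairwise Cohen's d
  (pooled-SD denominator). Complete-case per comparison; two-sided
  throughout; no multiple-testing correction across the nine parameters,
  mirroring the reporting convention of the study design this follows.
* **Permutation multivariate group test**: the published analysis used a
  bootstrap MATS MANOVA from an external package; the claim it supports
  (any joint group effect) is re-implemented here as a permutation test.
  The statistic is the sum of per-parameter F statistics — each F is
  scale-free, so parameters on different scales contribute comparably —
  and the null distribution permutes group labels over intact
  participant rows, with the add-one (Phipson–Smyth) tail probability.
  Its type-I error is verified to sit in [0.03, 0.07] at nominal 0.05
  over 200 null cohorts.
* **Inter-task correlations**: Pearson r between the TEA and GARDEN
  values of each parameter (task specificity / reliability).
* **Stepwise regression of the frailty score**: forward selection with
  entry p ≤ 0.05 and removal p ≥ 0.10 (the defaults of the statistics
  environment the original analysis was run in), a variance-inflation
  gate at 5.0 that skips collinear candidates, standardized betas, and
  R² / adjusted R². The recovery benchmark plants a predictor carrying
  exactly 25% of sample response variance — the observed effect size of
  the published task-average model — because at n = 27 the entry test's
  power against a *population* R² of 0.25 is only ≈0.8, so no selection
  procedure could meet a 90% recovery bar under that reading.

## Problem sizes and numerical choices

The test suite and the acceptance script use: n = 30 recordings per cell
for calibration checks; the reference composition 8/13/6 (with 5 seeds)
for end-to-end ANOVA recovery; 200 null cohorts × 2000 permutations for
the type-I check; 1000 cohorts for stepwise recovery; exhaustive peak
enumeration over all 3-letter series up to length 12; and 1000 random
signals against sum-based feature oracles at 10⁻⁹. Floating-point
degeneracies are handled explicitly: a constant response yields F = 0,
p = 1, η²p = 0 (not 0/0), and sums of squares below 10⁻¹² relative
tolerance are treated as zero. Irregular timestamps (>1% of intervals
off-nominal by >10%) are linearly resampled with a warning.

## Limitations

Gravity is removed as a constant, so low horizontal accelerations are
systematically attenuated — inherent to the method, not a bug. The
generator does not model limb trajectories, bimanual coordination,
gyroscope channels, task recognition, or vendor data formats. Trial
start/stop are the recording bounds. The regression stage models the
0–5 score as a continuous response, as in the original design; ordinal
models are out of scope.
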