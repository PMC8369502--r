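---
title: "Waveform analysis of optical cardiomyocyte recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveform analysis of optical cardiomyocyte recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(cardiowave)
```

## The measurement problem

High-throughput cardiac safety screens record the membrane potential of
spontaneously beating human iPS-cell-derived cardiomyocytes as a fluorescence
time series, one trace per well of a 96-well plate, sampled every 5 or 10 ms.
Ventricular-like control preparations (here "CT") beat slowly and show a
plateau-bearing action potential; retinoic-acid-derived atrial-like
preparations ("AM") beat roughly three times faster with a spike-like,
fast-repolarizing waveform. Drug effects are read out per well as the percent
change from the pre-compound baseline of a small set of waveform parameters,
and arrhythmia-like events — early afterdepolarizations (EADs), irregular
beating, and arrest — are tallied per condition.

`cardiowave` implements that entire readout as reusable, tested code:

1. a **simulator** that generates plate-format traces with known ground truth,
2. **beat analysis**: detection plus per-beat measurement of rate, amplitude,
   upstroke/decay velocity, and pulse-width durations (PWD) at fixed
   repolarization fractions, with Fridericia rate correction,
3. **event classification** into normal / irregular / EAD / arrest,
4. **dose–response tables** of percent changes and the associated statistics.

Raw recordings from plate readers are rarely shareable, so every stage is
validated closed-loop against the simulator's ground truth.

## Waveform parameters

For each beat, `t_activation` is the time of maximum upstroke velocity.
`PWD_x` is the time from activation until the signal has decayed `x` of the
way from peak back to the local diastolic baseline; the package measures
fractions 0.20–0.90 (the canonical screen reports PWD30/50/80). Because
spontaneous rate differs grossly between subtypes, durations are
rate-corrected per beat with the Fridericia (cube-root) convention carried
over from QTc analysis:

$$\mathrm{PWDcF} = \mathrm{PWD} / \mathrm{IBI}^{1/3},$$

with the preceding inter-beat interval IBI in seconds. `PWD30-80 =
PWD80cF − PWD30cF` summarizes late-repolarization width. The plateau
ratio

$$\frac{\mathrm{PWD40} - \mathrm{PWD30}}{\mathrm{PWD80} - \mathrm{PWD70}}$$

contrasts early versus late repolarization-interval widths: above 1 for
plateau (ventricular-like) morphologies, below 1 for spike-like
(atrial-like) ones, exactly 1 for a linear decay. (A ratio of the *mean
durations* rather than the *interval widths* would be bounded above by 1 for
any monotone duration profile and could not distinguish the two
morphologies.) Well summaries average all parameters over the beats whose
activation falls in the first 30 s of a recording phase — the standard
averaging window of the assay; where the window sits inside a longer
recording is a free choice, and the package uses the recording start.

## The synthetic-trace model

A well's clean signal is

$$y(t) = \Big[B + A \sum_i b(t - o_i)\Big] \cdot d(t), \qquad
d(t) = 1 - r_\text{drift}\, t / 60,$$

plus i.i.d. Gaussian noise with standard deviation
`noise_sd` · A. Drift is multiplicative because photobleaching attenuates
baseline and beat amplitude alike; a purely additive baseline ramp could not
exercise the amplitude side of detrending. Onsets $o_i$ are drawn with
inter-beat intervals $\mathrm{IBI}_i = \overline{\mathrm{IBI}}(1 + c_v z_i)$,
$z_i \sim N(0,1)$, floored so consecutive beats never overlap. All draws run
through counter-based sub-streams of the well seed, so injecting an event
never perturbs the onset or noise draws, and identical (preset, seed) calls
are bitwise identical.

The single-beat waveform $b(s)$ is a logistic upstroke (time constant
`upstroke_tau`, activation at its steepest point) multiplied by a
repolarization envelope that is 1 until the peak, then **piecewise linear
through the APD target knots** (level $1-f$ at time $\mathrm{APD}_f$),
continued by an exponential tail below the 90 % level, with corners rounded
by a 2-ms Gaussian. Two design points deserve comment:

* *Why not a sum of exponentials?* The calibration contract is to hit an
  arbitrary monotone seven-point duration profile to 1 ms; a low-order
  exponential family cannot interpolate arbitrary profiles and its
  least-squares fit can fail. The interpolating envelope hits the targets by
  construction.
* *Why piecewise linear with rounding, not a monotone cubic?* A monotone
  cubic through the same knots flattens at every knot, so the waveform
  approaches each measurement level at near-zero slope — tiny noise or
  amplitude error then moves the crossing by tens of milliseconds. The
  rounded-linear envelope crosses every level at a healthy slope, which is
  also what real optical action potentials do.

`calibrate_preset()` closes the loop: it renders a noise-free beat, measures
it with the package's own beat-analysis code, and nudges the knots by the
measured residual (damped, capped at 15 iterations, best iterate kept) until
every duration is within 1 ms; non-convergence is an error that reports the
residuals. Calibration is performed on a grid no coarser than 5 ms — a
sampler coarser than the knot spacing cannot pin durations to 1 ms.

### Phenotype presets

Presets store *corrected* duration targets (that is how plate readers report
them) and derive the uncorrected generation targets by inverting Fridericia
at the preset rate, so that the analysis pipeline's corrected outputs land on
the stored values. The defaults represent the two subtypes as characterized
on this platform: CT beats at 83.7/min with cAPD20/50/90 of 159.8, 315.5,
369.7 ms and plateau ratio 1.30; AM beats at 237/min with 69.8, 114.9,
156.1 ms and ratio 0.75. The intermediate fractions (30, 40, 70, 80 %) are
not part of the published characterization; the defaults (CT 230, 256, 330,
350 ms; AM 85, 97, 130, 146 ms) were fixed once as monotone interpolants
that realize the plateau ratios exactly.

Remaining defaults, chosen once at realistic plate-reader values: amplitude
1 (arbitrary units), baseline 10, noise_sd 0.02 (2 % of amplitude — optical
voltage signals on this class of reader are high-S/N), drift 0.02/min,
IBI jitter CV 0.02, upstroke tau 6 ms (CT) / 3 ms (AM).

### Drug effects and events

`drug_effect_model()` scales targeted parameters by Hill terms
$1 \pm E_\max c^h / (c^h + \mathrm{EC50}^h)$ — phenomenological by design; no
ion-channel kinetics are simulated. Effects are monotone in concentration and
vanish at $c = 0$.

Injected events mirror the three arrhythmia-like categories:

* **EAD** — a rapid secondary depolarization (3-ms logistic rise, 25-ms
  decay) added on the repolarization limb of a random fraction of beats,
  peaking where repolarization reaches the requested phase. The bump
  parameter is defined as the *prominence of the resulting secondary
  maximum* on the noise-free waveform; the raw transient is scaled to
  realize it (on a declining limb an unscaled bump realizes far less than
  its nominal height, which would make ground truth and detector evidence
  incommensurable).
* **irregular** — the same standard-normal IBI draws re-scaled to the
  requested CV (so requesting the preset's own jitter reproduces the
  un-injected trace bit for bit).
* **arrest** — all beats from the onset time onward removed, leaving
  baseline, drift and noise.

## Numerical choices in the measurement path

* **Noise estimate**: a low (20 %) quantile of |first differences|, scaled
  for Gaussian noise. Diastolic segments pin this quantile to the noise
  floor even though beat-driven differences contaminate the upper tail. A
  noise gate at 0.5 % of the beat amplitude switches the crossing and
  amplitude estimators between a clean path and a noise-robust path.
* **Activation time**: argmax of the first differences; step-like upstrokes
  (one dominant difference) pin to the steep sample so that an idealized
  instantaneous upstroke measures exactly at its jump; resolved upstrokes
  are refined by maximizing the derivative of a local cubic interpolant (a
  parabola through three differences is badly biased when the upstroke spans
  only a couple of samples).
* **Level crossings**: first crossing scan, then sub-sample refinement — on
  clean signals by root-finding on a local cubic interpolant; under noise by
  a local linear regression over ±max(10 ms, 2 samples) solved for the
  level. The window is kept tight because a wide secant fit picks up
  curvature bias on the convex approach to the tail.
* **Amplitude**: raw peak minus local diastolic baseline (median of the
  50-ms window ending 20 ms before activation) on clean signals; under noise
  the smoothed peak value is used instead, since a raw maximum is an
  extreme-value statistic that systematically overestimates.
* **Detrending**: rolling 10th-percentile baseline over three beat periods
  (period from an autocorrelation estimate, 1-s fallback), linearly
  interpolated and subtracted. Traces shorter than one window pass through
  with a warning.
* **Beat detection**: topographic prominence with a two-pass threshold
  (floor of five noise SDs, then 30 % of the median beat prominence) and a
  refractory lockout of half the median IBI (floor 100 ms). Beats without
  room for a baseline window or with unfinished terminal repolarization are
  discarded as edge-clipped.
* **Ground-truth slopes**: the sampled first difference depends on sampling
  phase, so the simulator records the phase-averaged maximum windowed slope
  at the trace's own sampling interval; measured per-beat maxima average to
  this value as beats realize quasi-uniform phases.

## Event classification

Thresholds are explicit in `classifier_config()` because the assay
literature names the categories but no quantitative criteria:

* EAD: secondary local maximum on the 30–95 % repolarization limb with
  prominence ≥ 5 % of amplitude (and ≥ 3.5 smoothed-noise SDs), half-prominence
  width ≥ 2 samples, after a light 15-ms moving average; a well is called
  EAD at ≥ 2 positive beats (a single positive among a hundred beats is
  treated as noise).
* irregular: IBI CV > 0.15 — scale-free across the threefold CT/AM rate
  difference; not evaluable below 5 beats.
* arrest: ≤ 1 beat in the window (tolerating one residual artifact peak).
* priority arrest > EAD > irregular > normal, one label per well, mirroring
  mutually exclusive incidence reporting.

At the default 2 % noise the false-positive EAD beat rate is below 1 %, and
on 120 simulated wells at 3 % noise (EADs injected in CT wells, where they
occur in practice; irregular beating in AM) sensitivity and specificity both
exceed 95 % — the packaged test suite recomputes exactly this. EAD transients
at the atrial spike-like rate are only a few milliseconds wide and are *not*
reliably separable from 5 % noise at 5-ms sampling; that regime is a
documented limitation, not a tested claim.

## Dose–response and statistics

Percent change is `100 (post − pre)/pre` per well; wells with an undefined
baseline are excluded (never counted as zero), and post-phase arrested wells
are excluded from parameter means while keeping their incidence
denominators. Tables report mean ± SD with the contributing n.

Two-sample comparisons follow the assay's convention: Shapiro–Wilk normality
checks, an F-ratio variance-homogeneity gate at α = 0.05 (the gate itself is
a documented, configurable choice), then Student's or Welch's t-test;
3+ groups get one-way ANOVA with Tukey HSD. All of these delegate to base R
(`shapiro.test`, `var.test`, `t.test`, `aov`, `TukeyHSD`); the test suite
cross-checks p-values against permutation oracles and verifies a 5 ± 2 %
type-I error rate over 500 null comparisons.

## Problem sizes and what the tests do (and do not) show

The packaged checks run single-CPU in about a minute: 30-s traces at 5-ms
sampling (≈ 6000 samples; 41 CT or 118 AM beats), 6–12-well incidence
fixtures, a 120-well classifier panel, and 500 null comparisons. These sizes
were chosen as the smallest at which every property is statistically
meaningful.

The simulator emulates subtype-specific morphology, dose-dependent parameter
shifts, Gaussian noise, linear photobleaching, rate jitter, and the three
event types. It does **not** emulate 1/f or photon-shot noise, calcium
transients or contraction artifacts, well-to-well biological variance
components (plating density, dye loading), conduction or spatial structure,
or time-resolved event dynamics within a 10-min recording. Green tests
therefore certify the *analysis pipeline* against the stated signal model —
they do not certify performance on optical recordings whose noise or
morphology departs from it.
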