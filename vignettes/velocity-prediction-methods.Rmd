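---
title: "Methods: predicting 30-15 IFT running velocity from accelerometry and heart rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting 30-15 IFT running velocity from accelerometry and heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velift)
```

## The problem

The 30-15 Intermittent Fitness Test (30-15 IFT) is an incremental shuttle-run
field test: 30-s runs over a 40-m course alternate with 15-s walking
recoveries, with the prescribed velocity starting at 8 km/h and rising by
0.5 km/h every 45-s stage. The velocity of the last completed stage
(V~IFT~) anchors high-intensity interval-training prescription, so knowing
the *instantaneous* running velocity matters — and GPS, the usual source,
is unreliable indoors. `velift` implements a pipeline that predicts stage
running velocity from body-worn sensors instead: two accelerometry-derived
external-load metrics — Player Load (PL) and Average Net Force
(AvNetForce) — plus heart rate (HR) as the internal-load signal, combined
by a z-scored linear-kernel support-vector regression (SVR) evaluated with
leave-one-subject-out (LOSO) cross-validation.

Because no raw data are publicly deposited for this design, the package
ships a synthetic-cohort generator that reproduces the protocol and the
between-subject statistical structure the analysis depends on, so every
stage of the pipeline is testable end to end.

## Load metrics

With raw axes $x, y, z$ in g (gravity included), per sample:

* **VMU** (vector magnitude units): $\sqrt{x^2+y^2+z^2}$.
* **Instantaneous net force**: body mass $\times$ VMU, with VMU converted
  to m s^-2^ (factor 9.80665) so the result is in newtons. The published
  formula multiplies mass by VMU without stating units; newtons are the
  only dimensionally coherent reading of a "net force" with a slope of
  order 130 N per km/h, so SI conversion is the default and a raw-g mode
  is kept behind `convert_g = FALSE` for device parity. **AvNetForce** is
  the mean over a 30-s run window; since gravity is not subtracted it
  carries a body-weight floor of about one g.
* **Player Load**: the printed formula is typographically corrupted
  (missing operator, unclear radical scope, a trailing 100). It is
  implemented as the standard accumulated form from the Player Load
  literature: per-sample root-sum-of-squares of successive-sample axis
  differences, summed over the window, divided by 100. Differencing makes
  PL insensitive to constant offsets (including gravity). Whether the
  original authors accumulated or averaged per sample is not recoverable;
  accumulation is the default and `per_sample_mean = TRUE` exposes the
  alternative. Differences spanning a masked gap are skipped, never
  bridged, so artifact removal cannot inject spikes.

## Preprocessing

The original analysis removed corrupted epochs by visual inspection of the
signal envelope. `velift` replaces this with a deterministic rule
(`envelope_mask()`): per axis, the residual about a 0.5-s moving median is
tracked by a 0.5-s moving maximum; samples whose envelope exceeds 6 times
the trace-wide median envelope on any axis are flagged, and flags are
dilated to whole 1-s epochs. Defaults (window 0.5 s, multiplier 6, at most
20% masked per window) are package choices — the manual step cannot be
automated faithfully, only reproducibly.

Windows are the 30-s run phases only, onset-aligned, half-open
`[run_start, run_end)`; recoveries are never windowed because velocity
labels exist only for runs. Window HR is a trimmed mean; the original
report names the trimmed-mean routine but not its percentage, so the
default is 20% (10% per tail, whole samples, rounded down), exposed in the
configuration.

## Model

Features (PL, AvNetForce, trimmed HR) are z-scored; velocity targets are
not. The regressor is an epsilon-insensitive linear SVR. Hyperparameters
are unreported in the source study; defaults are the conventional C = 1
and epsilon = 0.1 km/h, recorded in every report. Under LOSO, the scaler
and the SVR are refit on each training fold and applied to the held-out
subject, so no information leaks from the held-out subject into scaling
or fitting (a global-scaling mode exists behind `scale_scope = "global"`
for parity experiments only). Univariate baselines run the same machinery
with a single feature; an OLS estimator is available behind
`estimator = "ols"`.

Evaluation reproduces the published battery: Pearson correlation with the
Schober qualitative bands (cut-offs 0.1/0.4/0.7/0.9), OLS of predicted on
actual velocity, Bland-Altman limits of agreement (mean difference
$\pm\,1.96$ SD), a paired t-test, and Fisher r-to-z comparisons between
the multivariate and univariate correlations,
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/\sqrt{2/(n-3)}$.
The source study does not state which correlation-comparison test produced
its table of z statistics; this independent-sample Fisher formula
reproduces all three printed values (7.78, 10.43, 2.53) to two decimals at
n = 341 and is therefore adopted. A dependent-correlation variant would
need the predictor intercorrelation, which is not reported. Statistics
echoed against printed values are rounded half away from zero.

## The synthetic cohort generator

`cohort_spec()` defaults describe a 21-subject cohort calibrated to the
published descriptives: mass 71.93 ± 11.14 kg, resting/maximal HR
59.8 ± 8.53 and 197.07 ± 8.39 bpm, V~IFT~ 19.78 ± 0.94 km/h (snapped to
the 0.5 km/h grid), per-subject AvNetForce-velocity slope
132.46 ± 18.87 N per km/h, mean HR-velocity slope 3.92 bpm per km/h.
Draws are clamped normals except strictly positive quantities (HR
response, noise scale), which are lognormal with the stated arithmetic
mean and SD. All randomness derives from one cohort seed through
per-subject substreams, so enlarging a cohort never perturbs existing
subjects.

**Accelerometer model.** The signal is synthesised as magnitude times a
slowly wobbling unit direction, plus white noise per axis. During a run at
velocity $v$ the dynamic magnitude is
$(c + a_g v)\,(1-\cos\phi(t))$ g, where $\phi$ advances at the step
frequency, $a_g$ is the subject's accel slope in g per km/h and $c$ is a
subject-level "bounce" (dynamic amplitude at low speed — gait style).
Because the mean of $1-\cos$ is 1, the window-mean VMU is exactly
$1 + c + a_g v$: linear in stage velocity with slope $a_g$ by
construction, which is what makes parameter recovery a sharp test.
Shuttle turns appear every $\mathrm{shuttle\ length}/v$ seconds as 0.4-s
braking/re-acceleration couplets with zero net area, so turns add
realistic transients without biasing window means. Recoveries carry a
damped walking signal.

**Heart-rate model.** First-order kinetics
$\dot{\mathrm{HR}} = (\mathrm{HR}_{ss} - \mathrm{HR})/\tau$ with
$\mathrm{HR}_{ss}(v) = \mathrm{hr}_{min} + \beta_{HR}\, v$ clipped to
$[\mathrm{hr}_{min}, \mathrm{hr}_{max}]$, integrated exactly on the 1-s
grid. During a 15-s recovery HR relaxes toward an elevated post-exercise
level tied to the preceding stage (the stage velocity minus 3 km/h
equivalent), not to a walking steady state — 15 s is far too short to
approach one, and this keeps the stage-to-stage pattern shift-invariant.
HR starts at the fixed point of the per-stage map, the state a warmed-up
athlete entering stage 1 carries (the protocol prescribes a standardized
warm-up). Together these choices make window-mean HR *exactly* linear in
stage velocity whenever the hr~max~ clip does not bind, so noise-free
slope recovery is exact rather than approximate.

**Between-subject structure.** Free parameters the source study does not
pin down are set once, on physiological grounds, so that the study's
central qualitative findings are structural properties of the generator:

* The HR response draw (lognormal, mean 3.92, SD 0.7) is coupled
  negatively to resting HR through a 14 km/h reference velocity, so
  mid-test HR levels are comparable across athletes — a homogeneous
  trained cohort runs at similar relative intensity at a given speed.
  This keeps HR the strongest single predictor, as reported. The
  published between-subject SD of the HR slope (3.68) cannot be used
  directly under this linear-clipped HR model: it would saturate roughly
  a third of subjects at hr~max~ and make pooled HR prediction collapse,
  contradicting the study's own model-comparison table. The published SD
  most plausibly reflects saturating (nonlinear) individual responses
  that the prescribed linear model cannot represent.
* The bounce term (clamped normal, 0.4 ± 0.3 g, bounded [0, 1.2]) gives
  AvNetForce and PL realistic subject-level offsets at equal speed, which
  is what makes them weaker univariate predictors than HR, again as
  reported. A bounded draw is used because heavy-tailed gait outliers are
  not a feature of trained cohorts.
* Measurement noise: 0.05 g white noise per axis (scaled per subject),
  2 bpm HR observation noise, a 5% lognormal per-window amplitude jitter
  (stride-to-stride variability), and a slow autonomic HR drift (AR(1),
  SD 2 bpm, 60-s correlation time). Setting all noise SDs to zero yields
  analytically exact sessions.

With these defaults the emergent LOSO correlation ladder is approximately
multivariate 0.90 > HR 0.85 > AvNetForce 0.78 > PL 0.73, mirroring the
published ordering (0.91 > 0.87 > 0.73 > 0.62), and the predicted-on-
actual fit shows the published regression-to-the-mean signature (slope
below 1, positive intercept).

**What the generator does not emulate.** Real gait spectra and impact
transients; device orientation drift; HR artifacts from electrode
contact; test failure dynamics (V~IFT~ is set directly); the published PL
slope of 0.012 ± 0.005, which is dimensionally incompatible with the
accumulated-PL convention at 100 Hz given the force calibration — the
package's PL slope is an emergent ~0.5 AU per km/h instead; and the
published count of 341 windows from 21 subjects, which is arithmetically
inconsistent with the published V~IFT~ distribution (one session per
subject yields ~24-25 run windows each, about 515 in total; two pooled
sessions would give about 1030). Passing tests therefore demonstrate
correctness of the pipeline and faithfulness to the protocol and to the
reported between-subject structure — not that real 30-15 IFT data would
yield the same numbers.

## Numerical choices

* Stage velocities live on an exact 0.5 km/h grid; off-grid final
  velocities are rejected rather than rounded silently.
* All intervals are half-open `[start, end)` with time origin at stage
  1's run onset, so every sample belongs to exactly one phase.
* The envelope uses `stats::runmed` and an O(n) block-wise moving
  maximum; flagged samples are dilated to whole 1-s epochs.
* Degenerate inputs fail loudly: constant features refuse to z-score
  (naming the column), constant velocity refuses a fit, zero-variance
  differences in the paired t follow the t = 0 / infinite-t contract.
* The LoA multiplier is fixed at 1.96; trimming drops whole samples
  (floor), matching base R's `mean(trim = )`.

## Problem sizes used in the shipped checks

Unit tests run on short schedules (final velocities 8-10 km/h) and small
cohorts for speed. The acceptance battery runs the full default
conditions: 21 subjects at 100 Hz, ~515-530 windows per replicate, 50
seeded replicates for the stochastic ordering properties, and
3-5-subject mean-profile cohorts for exact parameter recovery. These
sizes were chosen so the whole battery completes comfortably on a single
CPU while leaving the stochastic assertions well-powered.

## Known limitations

* The SVR hyperparameters and scaler scope of the original analysis are
  unknown; defaults are explicit configuration, and conclusions that
  depend on them should be checked against the `ols` estimator and
  `global` scaling variants.
* The generator's linear HR drive is a deliberate simplification; it
  cannot express the saturating responses that likely produced the large
  published HR-slope SD.
* Real-data headline values (r = 0.91, the 0.85/1.81 fit, the specific
  limits of agreement, t = 1.386) are not reproducible without the
  original recordings; the package asserts their structural signatures
  instead.
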