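---
title: "Estimating hematoma age from hyperspectral skin reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hematoma age from hyperspectral skin reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A bruise (hematoma) changes color as extravasated hemoglobin is broken down
— oxyhemoglobin deoxygenates, heme is degraded to biliverdin and then
bilirubin — and a forensic examiner is routinely asked how old such a bruise
is. Visual dating is unreliable, so `hsibruise` implements an
examiner-independent alternative: record the skin's diffuse reflectance
spectrum over 400–1000 nm (204 bands) with a hyperspectral camera, reference
each hematoma spectrum against adjacent unaffected skin from the same frame,
and regress hematoma age on the normalized band intensities with an
L1-penalized (Lasso) linear model. Because no public recordings of this
design exist, the package ships a forward simulator that generates
study-shaped cohorts, and every claim below is demonstrated on that
synthetic data.

## From cube to feature matrix

A recording is a calibrated reflectance cube. Calibration divides raw counts
by a co-recorded white-reference tile per band,
`R = (raw - dark) / (white - dark)`; values above 1 occur under deliberate
overexposure and are kept. Two regions of interest — hematoma and nearby
unaffected skin — are averaged per band into one spectrum each
(`extract_mean_spectrum()`). Band index and wavelength are related linearly,
`lambda(b) = 400 + (b - 1) * 600/203` nm, so band 24 sits near 470 nm and
band 165 near 885 nm; the camera vendor's exact center table is not public,
and this linear convention is an explicit stand-in that reproduces the
band/wavelength correspondences the analysis relies on.

`normalize()` turns paired spectra into one of three feature sets: `raw`
(`h`), `subtract` (`h - s`), `divide` (`h / s`). The divide features have an
exact invariance that the others lack: both ROIs share one illumination
gain, which cancels in the ratio. This is the mechanism behind the empirical
ranking of the three normalizations under varying lighting. Skin reflectance
in this range is never near zero, so a divide reference below 1e-6 is
treated as a broken ROI and raised as an error rather than clamped.

## The age models

All models minimize the glmnet objective
`(1/2n) * RSS + lambda * ||beta||_1` on per-band standardized features, with
coefficients reported back on the original scale. The penalty weight is
chosen by inner cross-validation whose folds keep whole subjects together —
repeated measures of one subject are strongly correlated, and splitting them
across folds would leak. The grid is log-spaced over
`[1e-4 * lambda_max, lambda_max]` (100 points by default), where
`lambda_max` is the smallest penalty that zeroes every coefficient;
`rule = "min"` picks the MSE minimizer, `rule = "1se"` the sparsest model
within one standard error. Ages are handled in hours internally and reported
in days. Predictions are not clipped to the 0–21-day window by default, so
error statistics describe the unconstrained model; `cv_config(clip = TRUE)`
turns clipping on.

Three architectures are provided:

* **plain** — one Lasso on all samples;
* **hierarchical** — a gate decides whether a sample is younger or older
  than 7 days (168 h), then a phase-specific Lasso trained on `y <= 168` or
  `y >= 168` makes the estimate. Day-7 samples belong to both branch
  training sets, and a gate output of exactly 168 h routes old;
* **gender** — one Lasso per sex, routed by the recorded label.

### Why the gate is a classifier

The gate was genuinely open to two designs: a Lasso regression thresholded
at 168 h, or an L1-logistic classifier of old-vs-young. We ship both
(`cv_config(gate_variant =)`) but default to the classifier, for a reason
the simulator makes vivid: a fresh hematoma and a fully resolved one both
sit close to unaffected skin after ratio normalization. A squared-error gate
maps that shared corner of feature space to a mid-range age and routes
day-0 samples into the old branch, whose regressor then extrapolates to
~2-week estimates; on a default synthetic cohort this single failure mode
raised day-0 mean error from 3.6 to 17 days and the overall LOPO RMSE from
3.6 to 5.4 days. The two phases are nevertheless linearly separable (the
resolved spectra retain a few-percent bilirubin dip at ~470 nm that fresh
skin lacks), so the logistic gate separates them and the hierarchical model
then beats the plain one everywhere. The routing semantics are identical
for both variants.

## Evaluation

`run_experiment()` performs leave-one-subject-out cross-validation: one fold
per subject, trained on the other subjects, with an assertion inside the
loop that the held-out subject contributes no training rows. Reported
statistics are:

* pooled RMSE in days over all held-out predictions (the expected error for
  an unseen hematoma);
* per-subject mean absolute deviation (MAD), summarized per true-age window
  (young `<= 7 d`, old `> 7 d`, full) as across-subject mean M and sample
  standard deviation SD (n−1). Window membership follows the *true* age,
  boundary inclusive below.

The gender architecture restricts each training fold to the held-out
subject's sex and still pools one RMSE over both sexes.
`exclusion_rerun()` repeats an experiment with flagged recordings removed
from training folds only — the held-out predictions still cover every
recording — mirroring a post-hoc lighting-robustness check.

## The synthetic cohort

The generator emulates the study design the analysis was built for:
25 subjects (15 male, 10 female), a 3 ml standardized hematoma each,
recordings on days 0–7 daily and then every 48 h to day 21 (15 post-
injection timepoints, 375 model-usable recordings), visit times jittered
uniformly within ±2 h of schedule (applied consistently to generation time
and age label), one pre-injection baseline per subject.

The optical forward model is Beer–Lambert:
`R(lambda, t) = skin(lambda) * f_subj * exp(-A(lambda, t))` with

```
A = blood(t) * [f_oxy(t) * eps_oxy + (1 - f_oxy(t)) * eps_deoxy](lambda)
    + bilirubin(t) * eps_bil(lambda)
blood(t)     = b0 * (1 - exp(-t/2.5)) * exp(-t/8)      (peak ~3.6 d)
f_oxy(t)     = exp(-t/2)
bilirubin(t) = c_bil * (exp(-t/12) - exp(-t/3))        (peak ~5.5 d)
```

Extinction curves are sums of Gaussian bands peak-normalized to 1:
bilirubin at 465 nm (sigma 45 nm), oxyhemoglobin at 542/577 nm,
deoxyhemoglobin at 556/760 nm, and one broad near-infrared blood band at
900 nm (sigma 120 nm) shared by both hemoglobin species so that ~885 nm
attenuation tracks *total* blood content and its reflectance minimum falls
at the blood-kinetics peak (days 3–5) rather than drifting with the
oxygenation split. Amplitudes `b0 = 0.55` and `c_bil = 0.25` were chosen
once so that the ~470 nm ratio minimum falls between days 5 and 11, the
~885 nm minimum between days 3 and 5, and the day-21 spectrum returns to
within 5% of skin at every band — the qualitative phenomenology the
analysis assumes. These are documented modelling constants, not literature
extinction coefficients, and no claim of biophysical fidelity is made.

Per-subject variability is a lognormal intensity factor (sigma 0.3) on the
skin baseline; each recording draws a lognormal illumination gain
(sigma 0.15) shared by both ROIs and adds 1% relative Gaussian band noise.
A master seed spawns one sub-stream per subject, so enlarging the cohort
leaves existing subjects' draws untouched.

What the simulator deliberately does **not** model: melanin and skin-tone
variation beyond the scalar factor, spatial heterogeneity within the bruise
(margins vs. core), subject-to-subject kinetic differences, camera
push-broom geometry, and sensor saturation. Passing tests on this data
therefore demonstrate that the pipeline recovers structure it is designed
for; they are not evidence about human recordings.

## Numerical choices

* Coordinate-descent convergence (`thresh`) is glmnet's default `1e-7`;
  oracle-equivalence tests against ordinary least squares tighten it.
* The inner CV is an explicit loop over subject-grouped folds (held-out MSE,
  or binomial deviance for the gate), which keeps 2-fold selection possible
  when a training stratum holds few subjects.
* Fold assignments derive deterministically from the experiment seed; the
  same seed yields byte-identical prediction files.
* A zero-variance band keeps coefficient 0 at any positive penalty; a
  constant target is a refused degenerate input.
* End-to-end checks run the full 25-subject cohort with a reduced inner-CV
  budget — 3 inner folds and a 40-point lambda grid truncated at
  `1e-3 * lambda_max` (the selected penalties sit around
  `0.01-0.03 * lambda_max`, far above the cut) — which leaves RMSE values
  essentially unchanged while keeping a complete multi-seed comparison
  within minutes on one CPU; the package defaults remain 5 folds, 100
  points and a 1e-4 floor.

## Limitations

Under the simulator, subtracting the skin spectrum does not beat using
raw spectra: subject variability is a scalar intensity factor, so raw
features lose little age signal, while subtraction amplifies relative
measurement noise at the endpoints of the time course where hematoma and
skin coincide. With real cohorts, whose skin spectra differ in shape
(melanin, thickness), the raw features carry far more nuisance variation
than the simulator produces, and skin-referencing should matter more.

Ages are estimated by linear models on spectra whose kinetics are
non-linear in time; the hierarchical split absorbs only the dominant
(biphasic) non-linearity. The day-0/day-21 ambiguity of ratio-normalized
spectra is intrinsic: both extremes resemble unaffected skin, and with
noisier data than the simulator's the gate will start misrouting fresh
bruises again. All reported numbers are cross-validated on synthetic
cohorts; transferring the pipeline to real recordings requires re-fitting
and re-validating on measured spectra.
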