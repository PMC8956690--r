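---
title: "Estimating intracranial pressure from retinal vein photoplethysmography"
author: "veinppg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intracranial pressure from retinal vein photoplethysmography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 6, fig.height = 4.5)
library(veinppg)
```

## The measurement model

The central retinal vein crosses the lamina cribrosa on its way out of the
eye, so it separates two pressure compartments: the intraocular compartment
(pressure IOP) and the cerebrospinal-fluid compartment of the optic nerve
sheath, whose pressure tracks intracranial pressure (ICP). While IOP is
below the CSF pressure, venous transmural pressure inside the eye is high,
the vein sits on the stiff part of its compliance curve, and the cardiac
pressure pulse produces almost no visible calibre change. Once IOP is
raised above CSF pressure — here with an ophthalmodynamometer, a
contact-lens device whose ring force transducer converts to induced IOP by
the linear calibration

$$\mathrm{IOP}_{induced} = \mathrm{IOP}_{baseline} + 0.89 \times F,$$

the transmural pressure falls, the vein becomes compliant, and the pulse
amplitude of light transmission through the vessel grows approximately
linearly with IOP. Extrapolating that rising limb back to zero amplitude
gives the IOP at which the trans-laminar gradient vanishes: an estimate of
ICP in the sitting posture of the examination.

The package implements this chain end to end, together with a synthetic
phantom module that generates both amplitude curves and fundus video with
known ground-truth ICP, so every stage is verifiable without any external
data.

## Pulse amplitude from video: the harmonic layer

Green-channel video frames (25 fps by default) are analysed per pixel.
Intensity is converted to optical density by a Beer-Lambert transformation
with the pixel's own temporal mean as reference,

$$\mathrm{OD}(t) = -\log_{10}\!\big(I(t)/\bar I\big) \times 1000,$$

which removes static illumination heterogeneity without needing a
flat-field image. The factor 1000 fixes the package's arbitrary-unit (au)
scale: an optical density of 0.001 is 1 au. This scale is a declared
convention — the original au scale of the clinical instrument is not
recoverable — and every amplitude threshold in the package (the 6 au
amplitude floor, the 0.4 au/mmHg slope floor) is honoured on this scale and
exposed in `calibration_params()` for recalibration on other scales.

Each pixel's density series is regressed on a cardiac-locked two-harmonic
basis $\{1, \sin 2\pi f t, \cos 2\pi f t, \sin 4\pi f t, \cos 4\pi f t\}$,
with cardiac frequency $f$ the reciprocal mean inter-beat interval of the
oximeter beat timestamps and phase origin at the first beat. Two design
choices matter here:

* **Amplitude** is the peak-to-trough excursion of the fitted periodic
  component over one period, evaluated on a 2048-point grid. For a pure
  first harmonic this equals twice the coefficient magnitude; for mixed
  harmonics it is the visually meaningful excursion of the fitted waveform.
  The grid convention bounds the evaluation error at about $10^{-5}$
  relative, far below any physiological signal.
* **Quality filtering** uses the two-sided OLS t-test p-value of the
  first-harmonic sine coefficient, retained only when $p < 0.03$ (strict).
  A one-sided reading of "probability of the coefficient being greater than
  zero" would pass half of all pure-noise pixels, so the two-sided test is
  the only interpretation that makes the filter meaningful; under the null
  it passes 3% of noise pixels, which the tests confirm by simulation.

Frame registration is out of scope: stacks are assumed aligned (the phantom
generator produces aligned stacks), and no detrending beyond the constant
term is applied.

## From maps to pressure series

Retained amplitudes form a 2-D map mirroring the vessel anatomy. Hemivein
masks (superior and inferior halves of the vein tree) are manual inputs, as
in clinical practice. Two retention filters are applied before extracting
the one number a recording contributes: measures must lie within 0.8 mm of
the disk centre (straight-line, centre-to-centre, boundary inclusive —
signal-to-noise decays with eccentricity as the pulse wave attenuates), and
at least 20 measures must survive per hemivein, otherwise the recording is
rejected with a reason rather than an error. The maximum retained amplitude
per recording, paired with that recording's induced IOP, builds the
amplitude-versus-IOP series. Duplicate IOP settings are kept as independent
observations; all coordinates are 1-based (row, col) from the top-left.

## The three-phase estimator

The amplitude curve has three phases: flat (IOP below ICP), rising, and
plateau-to-falling at high IOP (the eye begins to limit venous inflow).
`icp_fit()` handles them in four steps:

1. **Peak truncation** — find the IOP at the global amplitude maximum and
   drop every pair at higher IOP. On ties the lowest IOP wins, which is the
   conservative choice: it drops plateau points rather than keeping them.
2. **Enumeration** — all windows of at least 3 consecutive pairs.
3. **Regression** — ordinary least squares of amplitude on IOP per window
   (`stats::lm`), unweighted; repeated IOPs are ordinary observations.
4. **Selection** — discard windows with Pearson $r < 0.8$ (signed, so
   negative-slope windows fail consistently), slope $< 0.4$ au/mmHg, or
   window maximum amplitude $< 6$ au; the amplitude floor is evaluated on
   the candidate window's own points, the most literal reading of the rule,
   with the whole-series alternative available by filtering beforehand.
   Among survivors the highest slope wins; ties go to the longer window,
   then the earlier start (longer windows are statistically steadier; the
   tie rule is otherwise arbitrary and documented rather than hidden).

The winner's x-intercept $-b/m$ is the estimated sitting ICP. It is
deliberately not clipped: estimates below zero or above the window's
minimum IOP are reported as-is so that out-of-range physiology surfaces in
the report instead of being silently altered. A series with no surviving
window is an *exclusion* carrying one of two reasons mirroring the two
clinical failure modes: `"flat amplitude slope"` (typical of advanced
papilloedema compressing the vein — the subject-level report then alerts
that elevated ICP is likely) or `"max amplitude < 6 au"`. When peak
truncation leaves fewer than three pairs the same two categories apply
(low-amplitude if the curve never reached the floor, flat otherwise).

Per-dataset intercepts — up to four per subject, superior and inferior
hemiveins of both eyes — are averaged arithmetically by
`combine_subject()`. Posture is handled explicitly throughout: the
examination is seated, so intercepts are sitting-convention; comparison
against lumbar puncture in the lateral decubitus position adds a fixed
offset,

$$\mathrm{ICP}_{LD} = \mathrm{ICP}_{sitting} + 10\ \mathrm{mmHg},$$

while comparisons against seated EVD readings skip it. The fixed offset is
a known limitation: the true postural difference varies with torso length.

## Concordance statistics

`agreement()` implements Bland-Altman method comparison with differences
oriented estimated − invasive: mean and sd of differences, limits of
agreement $\bar d \pm 1.96 s$, and the large-sample confidence half-width
$1.96\, s \sqrt{3/n}$ on each limit. That approximation, rather than the
exact t-based form, is the one under which a pilot sd of 3.8 mmHg and a
target half-width of ±2.5 mmHg yield a 27-subject design
(`loa_sample_size(3.8, 2.5)`), so it is the form the package standardises
on. Moment skewness and kurtosis (Pearson convention, normal = 3) describe
the difference distribution; normality testing is delegated to
`stats::shapiro.test`. `diagnostic_performance()` evaluates the two fixed
clinical cut-offs — 14.7 mmHg (borderline, 20 cmH₂O) and 18.4 mmHg
(pathological, 25 cmH₂O) — with strict inequalities and explicit flags for
undefined rates. No ROC machinery and no bootstrap intervals are provided.

## The phantom generator

The synthetic module defines the study conditions under which the package
verifies itself; its defaults are fixed, not tuning knobs.

* **Amplitude law**: continuous piecewise-linear — flat at `baseline_amp`,
  rising at `rising_slope` from `icp_true` to `peak_iop`, falling at
  `fall_slope` above, floored at zero. Defaults: baseline 0 au (the
  flow-discontinuity theory has amplitude tending to zero at the balance
  point, and no baseline magnitude is reported for real eyes — a documented
  assumption that also makes the rising-limb x-intercept exactly equal to
  `icp_true`), rising slope 1.2 au/mmHg, peak 30 mmHg above the knee (so
  that even a sitting ICP of −5 mmHg, the bottom of the simulated clinical
  range, leaves three rising-phase points on the protocol grid), fall slope
  0.6 au/mmHg, noise sd 0.5 au.
* **Protocol**: IOP from 15 to 45 mmHg in 5 mmHg steps (data below
  ~15 mmHg is not obtainable in practice), 25 fps, at least 3 cardiac
  cycles per step, cardiac frequency 1.2 Hz (72 bpm) with noiseless beat
  times (jitter is a configurable extension, off by default).
* **Video**: vessel pixels oscillate in optical density with a two-harmonic
  waveform (first:second amplitude ratio 2:1, fixed phases — the analysis
  model is thereby correctly specified, which is the point of a phantom)
  normalised to unit peak-to-trough, scaled so the injected peak-to-trough
  amplitude in au equals the law's value times the pixel's weight.
  Intensity follows Beer-Lambert around $I_0 = 200$ on an 8-bit-like
  scale; Gaussian OD noise lands on every pixel, so off-vessel pixels carry
  noise only. The falling phase is linear because only the rising phase
  enters estimation — the shape above the peak merely has to create a
  detectable maximum.
* **Cohorts**: up to four series per subject; ground truth is stored in
  both posture conventions explicitly, so no test can confuse them.
* Noisy curve-level amplitudes are *not* clipped at zero: the generator's
  contract is law + Gaussian noise, which the noise-calibration tests rely
  on. Pipeline-produced amplitudes are nonnegative by construction
  (peak-to-trough), so the container tolerates small negatives only from
  the synthetic path.

What the phantom does not emulate: venous wall biomechanics, eye movement
and frame misalignment, heart-rate variability, illumination drift, and
manual outlining error. Passing the round-trip tests therefore shows the
pipeline is internally correct and well calibrated under its own model
assumptions; it does not certify performance on real fundus video, where
registration quality and model misspecification dominate.

## Numerical behaviour and verification scale

With zero noise, a baseline of 0 au and at least three grid points strictly
inside the rising phase, the full curve-level chain returns `icp_true` to
machine precision: every pure rising-phase window has exactly the same
slope, the tie-break picks the longest, and its intercept passes through
$(\mathrm{icp\_true}, 0)$. The video chain adds one second-order
approximation — the per-pixel mean intensity as Beer-Lambert reference —
whose relative amplitude error is about $(\ln 10 \cdot \mathrm{OD})^2/2
\approx 3 \times 10^{-4}$ at 10 au, so video round trips are verified at
the 1% level and end-to-end ICP recovery through video at 0.05 mmHg.

The test-suite problem sizes were chosen to keep the full suite fast while
leaving comfortable statistical margins: phantoms of 8–48 px on a side,
cohorts of 30 subjects, 300–1000 random instances per brute-force oracle
comparison, 600–2000 simulated pixels for the null-calibration checks. On
the stochastic cohort (30 subjects, noise 0.5 au, LD truth uniform on 5–30
mmHg) the estimated-versus-true regression sits near slope 1.03–1.05 with
r ≈ 0.998 and a mean bias below 1 mmHg; the small upward slope bias is the
expected price of selecting the highest-slope window and shrinks with the
number of datasets averaged.

## Worked example

```{r example}
# a subject with true sitting ICP 14 mmHg (24 mmHg lateral decubitus)
law <- amplitude_law_params(icp_true = 14, noise_sd = 0.5)
series <- synth_pressure_series(law, protocol_params(), seed = 7)
fit <- icp_fit(series)
fit
plot(fit)
```

```{r cohort}
cohort <- synth_cohort(12, icp_sampler = function(n) runif(n, 0, 18),
                       seed = 11)
est <- estimate_cohort(cohort)
agreement(data.frame(invasive = est$invasive, estimated = est$estimated))
```

## Known limitations

* The au scale is a package convention; transferring the 6 au and 0.4
  au/mmHg thresholds to another acquisition chain requires recalibration
  (they are parameters, not constants).
* The fixed +10 mmHg postural conversion ignores torso-length variation.
* No frame registration: misaligned video must be registered upstream.
* The estimator assumes the flat-phase amplitude is near zero; a large
  true baseline amplitude would bias the x-intercept low by
  `baseline_amp / rising_slope` mmHg.
* Exhaustive window enumeration is quadratic in series length — irrelevant
  at the 7–10 steps of a clinical protocol.
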