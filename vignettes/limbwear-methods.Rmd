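---
title: "Methods: harmonized upper-limb accelerometry variables and their reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized upper-limb accelerometry variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`limbwear` turns bilateral wrist-worn triaxial accelerometer recordings into
25 harmonized movement variables and the cohort statistics that describe
their measurement properties. This vignette is the package's account of the
underlying methods: the signal model, the choices that were genuinely open
and how they were resolved, what the synthetic generator does and does not
emulate, and the numerical conventions that make results reproducible.

## Signal model and processing chain

A recording is one limb-day of triaxial acceleration in gravitational
units, nominally 30 Hz, from a wrist device with a ±8 g dynamic range.
Two analysis streams are derived.

**30 Hz magnitude stream.** Each axis is bandpass filtered 0.2–12 Hz and
collapsed to the vector magnitude. The band's purpose is to remove constant
linear acceleration — gravity, riding in a vehicle — while keeping the
frequency range of human arm movement. The filter is a Butterworth with 4
poles total applied forward and backward (`signal::filtfilt`), so the phase
response is identically zero; the measured passband gain at 3 Hz is 0.95
and DC is attenuated by far more than 40 dB. Zero phase matters because
jerk is a first difference: a phase-distorting filter would bias it.

**1 Hz count stream.** Activity counts are produced by an open
reconstruction of the ActiGraph counting chain, applied per axis at 30 Hz:
bandpass 0.25–2.5 Hz, rectification, saturation at 2.13 g, a 0.068 g
dead-band, quantization at the 8-bit step 2.13/128 g, decimation to 10 Hz,
and accumulation over each second. The vendor's exact algorithm is
proprietary, so these counts are *approximately* ActiLife-equivalent, and
the reconversion κ = 0.001664 g per count — applied to the vector magnitude
of the per-axis counts — is itself an approximation; both facts are
inherent to working in device-independent units rather than defects of this
implementation. A second is classified **moving** when its
vector-magnitude count reaches 2 (the boundary second counts as moving;
the convention is exposed as `tau` in `conversion_constants()`).

One reading deserves a note: the count band 0.25–2.5 Hz is described in
source material as applied to "1 Hz data", which is above that series'
Nyquist limit. It is implemented here the only physically coherent way:
the band belongs to count *generation* from the high-rate stream, exactly
where the ActiGraph chain applies it, and the 1 Hz series is the
accumulated output.

## The 25 variables

Durations are pure set arithmetic over per-second moving flags (union,
intersection, differences, each divided by 3600), so the additivity
identities hold exactly by construction. Intensity uses the median of the
count-derived magnitude over moving seconds per limb — medians because
per-second magnitudes are right-skewed — their sum across limbs, and the
maximum over all *valid* seconds for the peak (the peak deliberately scans
still seconds too: a single vigorous second below the bout threshold on
average is still the day's peak). Symmetry is the ND/D ratio of durations,
medians, and moving-second SDs, and the bounded jerk asymmetry index.
Complexity covers the moving-second SD, sample entropy, average jerk, and
the two spectral moments.

Choices that the source definitions leave open, resolved here:

* **Sample entropy parameters.** m = 2 and r = 0.2 × segment SD, the
  field-standard defaults for physiological series; both are exposed in
  `complexity_params()` and echoed into output provenance. Because the
  parameters are conventions, absolute entropy values are comparable only
  within a fixed parameterization.
* **Entropy input.** The 1 Hz count-magnitude series of the hour of
  maximum activity, with the hour chosen by the largest 3600 s sliding-
  window sum of vector-magnitude counts (1 s steps, ties to the earliest
  start). A constant segment has entropy 0 by convention; if no template
  pair matches at length m + 1 the value is `Inf` and flagged saturated.
* **Peak magnitude source.** The 1 Hz count-magnitude stream, keeping all
  intensity variables in a single unit chain.
* **Jerk/spectral moving mask.** Movement is defined at the epoch level
  only, so a 30 Hz sample inherits the moving flag of its enclosing
  second; jerk averages |Δvm|·f_s over sample pairs whose epochs are both
  moving.
* **Spectral estimator.** "Power-weighted mean and SD of the component
  frequencies" names no estimator, so the package uses an averaged
  modified periodogram: moving samples are concatenated, cut into 60 s
  Hann-tapered demeaned windows with 50 % overlap, and the averaged
  spectrum is restricted to 0.2–12 Hz before the weighted moments are
  taken. Demeaning plus the Hann taper confines the large DC component of
  a rectified magnitude signal to bins below the 0.2 Hz cut. Concatenating
  bouts introduces splice discontinuities; their broadband leakage is
  small relative to genuine movement power but is the reason the planted-
  frequency recovery test uses long bouts.

## Wear time, gaps, and undefined values

A day is included when the shorter limb has **strictly more than 10 h** of
valid epoch-seconds; sleep is deliberately not excluded. Wearing-time
confirmation by visual inspection cannot be a library primitive, so the
package replaces it with an explicit mask: epochs covered by fewer than
half the nominal samples (empty seconds, gap interiors) are invalid and
excluded from every variable; inter-sample gaps over 1 s are logged.
Variables whose preconditions fail (a limb with no moving seconds, a zero
dominant denominator, fewer than 3600 valid seconds for entropy) are
carried as flagged missing values with a reason — never silently zero —
and the cohort statistics are missing-aware per variable (pairwise
deletion), so one undefined variable does not discard a day's other 24.

## Cohort statistics

All correlation and sex analyses run on subject-averaged values (one
observation per participant). Sex comparisons are Welch t tests — the
unequal-variance form is the safer default when group variances are not
known to match — reported as female − male. ICC(2,k) is the two-way
random-effects, absolute-agreement, average-measures form computed from
the mean squares, `(MS_R − MS_E)/(MS_R + (MS_C − MS_E)/n)`. With unbalanced
2–4 day protocols the closed form needs a rectangular matrix; each subject
is truncated to the minimum common day count (earliest days first), and a
variance-components ICC fitted on *all* days by a crossed random-effects
model is reported alongside, since the truncation rule is a choice rather
than a given. Day-to-day variation is the residual SD of the REML mixed
model with a cubic age polynomial (orthogonal basis, to avoid the
collinearity of raw powers; the degree degrades gracefully when a cohort
has fewer than four distinct ages), sex, a linear day effect, and a random
subject intercept. The coefficient of variation is the per-subject
SD/mean across days, averaged over subjects and reported as a percentage;
subjects whose mean is numerically indistinguishable from zero (|mean| <
1e−8) are excluded with a warning because the ratio diverges — the same
inflation that makes the CoV of a near-zero-mean index uninterpretable no
matter the implementation. Every family of tests is flagged at the
Bonferroni threshold 0.05/25 = 0.002.

## The synthetic generator

`generate_cohort()` exists so that every stage — file I/O, counting,
classification, variable extraction, cohort statistics — can be validated
against known ground truth. Its design goal is *analytic* truth, not
physiological realism:

* **Bouts.** Each limb's movement is an alternating bout/rest process with
  shifted-geometric dwell times (minimum 3 s), dominant-limb occupancy
  ~0.42 of the day in ~30 s bouts. A dominant bout is shared by the other
  limb with probability 0.79 (controlling simultaneous vs. isolated time),
  and isolated non-dominant bouts fill dominant rest so that the expected
  ND/D duration ratio equals the planted use ratio 0.96. Still gaps
  shorter than 3 s between bouts are closed before the tally — the filter
  ring-down from both neighbours would classify them as moving anyway.
* **Emission.** During bouts the two in-plane axes carry a quadrature pair
  `x = A(t)cos ωt, y = A(t)sin ωt`, so the vector magnitude equals the
  envelope `A(t)` identically; the envelope is a lognormal per-bout
  amplitude (median 0.25 g, floor 0.12 g) modulated at the planted
  movement frequency (default 3.4 Hz, depth 0.8) with raised-cosine 1 s
  onsets/offsets. The carrier sits at 1.5 Hz, inside the count band, so
  every bout second registers counts. Gravity is a constant 1 g on the
  third axis — exercising the DC-rejection path — plus 0.005 g white
  sensor noise everywhere, below the count dead-band so quiescent seconds
  register exactly zero counts. Together these make the planted movement
  mask *exactly* recoverable by the count chain, which the tests assert
  seed by seed.
* **Cohort structure.** Log amplitude, logit occupancy, and modulation
  frequency each carry a subject-level and a day-level Gaussian effect and
  a linear age slope (negative by default, emulating the gentle decline of
  activity through adolescence); demographics default to ages uniform on
  3–17, 52 % male, 94 % right-handed, 2–4 days per subject of 24 h each.
* **What it does not emulate.** Gesture content, circadian/sleep
  structure, device noise beyond white noise, autocalibration error.
  Passing recovery tests therefore demonstrates that the *computational
  chain* is correct and self-consistent — not that the variables are
  accurate for any particular clinical population.

`simulate_cohort_table()` bypasses signals entirely and draws one variable
straight from the mixed model (planted between-subject and residual SDs,
age/sex/day effects); it is the right tool for validating the statistical
battery at realistic cohort sizes, where synthesizing 600 days of 30 Hz
signal would add cost but no information about the estimator.

## Numerical conventions

* Epochs are 0-based half-open 1 s bins anchored at the recording start;
  bilateral alignment trims to the common overlap on whole-second
  boundaries. Missing hand dominance is treated as right.
* Filtering pads with the odd reflection of the signal about its
  endpoints before `filtfilt`, so a constant input pads to a constant and
  gravity leaves no boundary transient (without this, the first and last
  seconds of every recording classify as movement).
* Stored samples live on the canonical 1e-6 g decimal grid as realized by
  the text parser (`quantize_g()`), making CSV round trips bit-identical;
  1e-6 g is ~3 orders of magnitude finer than the device's own
  resolution.
* Ties in the maximum-activity hour break to the earliest start. Sliding
  is in 1 s steps; invalid seconds contribute zero to window sums.
* Resampling to 30 Hz (for other native rates) is linear interpolation on
  a uniform grid, adequate for near-uniformly sampled device output.

## Problem sizes

The test suite runs generated days of 1200–4000 s for identities and
pipeline properties, one 36 000 s (10 h) day for the planted intensity-
scale recovery, a 200-subject × 3-day table-level cohort for mixed-model
recovery, and a 3-subject × 2-day end-to-end determinism run; these sizes
were chosen as the smallest at which each property is cleanly identified.
The acceptance script reports the use ratio of a mirrored-limb day
(3600 s), the jerk asymmetry index of identical limbs, and the maximum
|index| over 1000 random jerk pairs.

## Known limitations

Counts are not bit-exact ActiLife output, so absolute intensity values can
differ slightly from vendor-software pipelines; entropy values depend on
the (m, r) convention; the GT3X binary container is not parsed (export to
delimited text first); non-wear detection beyond the validity mask,
time-zone arithmetic, and device calibration are out of scope. ICC
estimates from very small cohorts are noisy and can leave [0, 1], as the
closed form does not constrain them.
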