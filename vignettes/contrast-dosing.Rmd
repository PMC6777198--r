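---
title: "Individualized contrast dosing for CT aortography: model, simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized contrast dosing for CT aortography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortadose)
```

## The problem

CT angiography of the aorta has traditionally used a fixed contrast bolus —
120 ml is a common institutional standard — even though arterial enhancement
depends strongly on patient habitus (larger patients dilute the same iodine
load over a larger blood volume) and on circulation (a faster heart
rate / higher cardiac output clears and dilutes contrast faster). An
injector-side calculator can individualize the volume from two bedside
quantities, body surface area (BSA) and heart rate, and a three-arm pilot
design can then ask whether the individualized dose — and an additional 50%
dilution of it — preserves aortic enhancement and diagnostic image quality
while lowering the iodine burden.

`aortadose` implements that calculator bit-for-bit and wraps it in a fully
seeded simulation of the three-arm study: synthetic cohorts, per-patient
enhancement at five aortic measurement levels, two-reader visual grading,
a CT-like phantom with circular-ROI measurement, and the group statistics.

## The dose algorithm

For a patient with weight $w$ (kg), height $h$ (cm), heart rate $r$ (bpm)
and stock iodine concentration $c$ (mg I/ml), the administered volume is

$$V = \mathrm{clamp}_{[40,\,150]}\Big(\big[\mathrm{BSA}(h,w)\cdot 45
  + \Delta_{\mathrm{HR}}(r) + \Delta_{\mathrm{conc}}(c)\big]\Big)\ \mathrm{ml},$$

with the sum rounded half-up to whole ml before clamping. The heart-rate
correction $\Delta_{\mathrm{HR}}$ is piecewise constant
($\le$55: −10; 56–65: 0; 66–75: +10; 76–90: +20; 91–105: +25; >105: +30 ml)
and $\Delta_{\mathrm{conc}} = 2\,(350 - c)/10$ ml. The dilution arm
administers $\max(\mathrm{round}(V/2),\,20)$ ml.

### The two BSA readings

The device documentation prints BSA as $((h \times w)/3600) \times 0.5$.
Taken literally this is not a recognised anthropometric formula — the
Mosteller formula is $\sqrt{hw/3600}$, and the printed "$\times\,0.5$" is
plausibly a typeset corruption of the exponent $0.5$. Both readings are
implemented (`bsa_mode = "literal"` / `"mosteller"`). The package default is
**literal**, because only the literal reading reproduces the device's
documented worked example:

```{r worked-example}
calculate_dose(115, 185, 122, 350)
```

Under the Mosteller reading the same patient would get
`r round_half_up(compute_bsa(115, 185, "mosteller") * 45 + 30)` ml — nowhere
near the documented 163 ml. The literal reading behaves like Mosteller
squared (it grows linearly in $hw$), so it over-doses very large patients
relative to Mosteller; the clamp at 150 ml bounds the consequence. The two
readings agree exactly when $hw = 14{,}400\ \mathrm{kg\,cm}$ (both give
2.0 m²) and the literal value exceeds Mosteller exactly when $hw/3600 > 4$.

Two other boundary decisions are baked in and tested: a heart rate of
exactly 55 bpm falls in the −10 ml band (the printed table skips from
"<55" to "56–65"; implementing the low band as $\le 55$ makes the lookup
total), and all corrections are applied *before* the clamp, with the
dilution applied *after* it (consistent with the observed dilution-arm
maximum of 72 ml $= \mathrm{round}(144/2) \le 150/2$).

## The synthetic cohorts

No patient-level data are available, so the cohort generator is the study
stand-in. Each arm's weight, height and heart rate are drawn independently
from normal distributions truncated to the reported per-arm ranges, with the
reported arm means and SDs as the pre-truncation parameters
(`study_demographics()`; n = 20 per arm). Sampling is by inverse CDF, so a
fixed seed gives one reproducible cohort regardless of the bounds.

Two deliberate simplifications, stated rather than hidden:

* The reported moments describe the *observed* (bounded) data; using them as
  pre-truncation parameters shrinks the simulated SD slightly and shifts the
  mean toward the center of an asymmetric range (e.g. the dilution arm's
  truncated weight mean is 81.5 kg for a nominal 79.9). This is left
  uncorrected for the demographics: the effect on simulated doses is well
  inside the arms' sampling noise.
* Attributes are sampled independently by default. Real weight and height
  correlate; `weight_height_cor` imposes a Gaussian-copula correlation while
  preserving both truncated marginals, for users who care about BMI realism.
  The default 0 keeps the literal reported marginals.

## The outcome generator

Enhancement is simulated *distributionally*, not pharmacokinetically: each
patient's mean aortic enhancement is one draw from the arm's truncated
normal, and the five measurement levels (coeliac trunk, renal, infrarenal,
both common iliacs) add independent level noise (`level_sd`, default 12 HU —
a within-patient spread consistent with measuring the same bolus at five
stations). Here, unlike the demographics, the generator **moment-matches**:
the pre-truncation location is solved (by `uniroot` on the analytic
truncated-normal mean) so the *truncated* mean equals the reported group
mean. Without this, naive truncation of the dilution arm's
N(191.2, 79.3²) to [79.1, 449.1] would have mean ≈ 203.7 HU and every
calibration downstream would inherit a ~12 HU bias. A mechanistic mode
(enhancement ∝ iodine mass / BSA with a $\sqrt{r_\mathrm{ref}/r}$ heart-rate
factor) ships for sensitivity exploration only; it is a toy kernel, not a
validated model.

Visual scores use a latent-quality model: a monotone piecewise-linear map
carries mean enhancement to a continuous quality, readers add independent
N(0, 0.4²) noise (score units), reader 2 adds a systematic per-arm bias
(+0.45, +0.45, +1.1 — the consistently-higher second reader of the study),
reader 1's second session perturbs the first-session latent by N(0, 0.35²),
and the observed grade is the latent rounded half-up and clipped to 1–5.
The four HU knots of the map were calibrated **once**
(`scripts/calibrate_thresholds.R`: Nelder-Mead on 40,000 simulated patients
per arm, seed 2026) so the reader-averaged arm means reproduce
4.5 / 4.6 / 3.7, and frozen at (81.19, 144.88, 206.55, 259.77) HU. The
calibration achieved expected means of 4.53 / 4.57 / 3.70; the residual
0.03 gap between the first two arms is irreducible in this model because
the calculator arm's enhancement distribution is slightly *below* the
standard arm's while its target score is slightly above — a reminder that
the reported scores carry reader information beyond enhancement.

What the generator does **not** emulate: reader agreement magnitudes. With
quality driven by enhancement alone, the two simulated readers share most of
their signal, and the default inter-/intra-observer ICCs come out around
0.75 / 0.9 — higher than the reported 0.472 / 0.601, which reflect genuine
reader idiosyncrasy that cannot be recovered from group summaries. Passing
tests therefore certify the *machinery* (the ICC estimator against a
brute-force ANOVA oracle, bias-invariance of the consistency form,
monotonicity of scores in enhancement), not agreement realism. Likewise the
dissection true-lumen fraction defaults to 1: the reported distributions
already include dissection patients, and attenuating them again would
double-count; the knob exists for what-if runs.

## The phantom

`render_slice()` paints an axial CT-like slice (default 128² pixels at
0.7 mm): circular lumen on a 40 HU background, optional mural thrombus ring,
optional dissection flap. The flap is a straight strip whose offset from the
lumen centre is solved from the circular-segment area equation so the true
lumen holds exactly the requested area fraction. `auto_place_roi()` mirrors
the clinical procedure — a circular ROI centred in the (true) lumen — as the
centroid of the true-lumen mask with radius 0.6× the largest centroid-centred
inscribed circle (the 0.6 is a package convention; the clinical ROI size was
operator-chosen and unreported). A true lumen too small for a 1.5 mm ROI is
an error, never a silently shrunken measurement.

Measurement is a pixel-centre-in-disc test with no partial-volume weighting
— simple, deterministic, and exactly reproducible by brute-force pixel
enumeration (the oracle in the test suite). Consequences: sub-pixel ROIs can
be empty (an error), and measured means on noise-free slices are exact while
edges contribute nothing fractional. Partial-volume smoothing is a known
omission, acceptable because every package use of the phantom measures ROIs
well inside uniform regions. Coordinates are 0-based, row-major,
pixel-centre convention; export is lossless CSV or windowed PNG (DICOM is
deliberately unsupported).

## The statistics

`describe()`, `percent_difference()`, `two_sample_ttest()` and
`icc_consistency_average()` are written out from first principles — this
module *is* the analysis surface — and each is tested against an independent
oracle (`stats::t.test`, explicit double-loop ANOVA sums of squares,
numerical integration for truncated moments).

Decisions a maintainer should know:

* The study protocol calls its test "paired" yet compares independent arms.
  The package default is the **pooled two-sample Student t**; `"paired"` is
  reserved for genuinely paired intra-patient data, and `variant = "welch"`
  reruns every comparison without the equal-variance assumption. At equal
  arm sizes the pooled and Welch *statistics* are identical; only the
  degrees of freedom (and hence p, mildly) differ.
* Significance is hard-coded at p < 0.025 (a Bonferroni α/2), with no
  further correction across outcome variables, matching the protocol.
* ICC is the two-way, **consistency**, average-measures form
  ICC(C,k) = (MS_rows − MS_error)/MS_rows. Consistency (not absolute
  agreement) is the right form here because it is invariant to a systematic
  additive reader offset — exactly the reported reader-2 behaviour. Zero
  between-subject variance makes the estimand undefined and is reported as
  such (`defined = FALSE`), never as NaN.
* Percent differences are computed from unrounded means and rounded half
  away from zero for reporting; two of the reported score percentages are
  inconsistent with their own rounded means and are not targeted.
* Degenerate t-test inputs follow stated conventions: two constant samples
  with equal means give t = 0, p = 1; unequal constant means give p = 0.

## Determinism and problem sizes

Every random quantity takes an explicit seed; there is no wall-clock
seeding. The pipeline derives module sub-seeds by mixing the master seed
with an FNV-1a hash of the stream name, so adding a stage never perturbs
existing streams, and `run_pipeline()` is byte-identical across reruns.
Outputs are written via write-then-rename, so an interrupted run leaves no
truncated files. The test suite exercises the generators at the study's own
scale (n = 20 per arm) plus convergence checks at 4,000–20,000 draws and a
40-replicate parameter-recovery study; the full suite runs in well under a
minute.

## Known limitations

* The literal BSA reading is not anthropometric; it is kept because it is
  what the device computes. Cross-study comparisons should use Mosteller.
* Enhancement is distributional: dose and enhancement are linked only
  through arm membership, not through each patient's administered iodine
  (use the mechanistic mode to explore that coupling qualitatively).
* Reader-agreement magnitudes are not calibrated (see above).
* The phantom is 2-D, noise is white Gaussian, and there is no acquisition
  physics (no helical sampling, kernels, beam hardening, or bolus timing).
* Two reported doses (126 and 134 ml) match neither BSA reading under any
  stocked concentration; the protocol allowed technician adjustment, so they
  are treated as manually adjusted and not used as checks.
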