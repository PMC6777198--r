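# aortadose

Individualized contrast-agent dosing for CT angiography of the aorta, plus a
fully seeded simulation of the three-arm pilot study built around it.

## The problem

CT aortography classically injects a fixed contrast volume (120 ml in many
institutions) regardless of patient size or circulation. Arterial
enhancement, however, scales with body surface area (BSA) and is diluted
faster at higher heart rates. An injector-side calculator can individualize
the volume from those two bedside quantities:

```
V = clamp[40, 150]( round( BSA(h, w) · 45 ml/m²  +  Δ_HR(r)  +  Δ_conc(c) ) )
```

* `BSA(h, w)` — two readings are implemented: the device's **literal**
  formula `(h·w / 3600) · 0.5` (the default; it reproduces the device's
  documented worked example) and the standard **Mosteller** formula
  `sqrt(h·w / 3600)`.
* `Δ_HR` — piecewise heart-rate correction: ≤55 bpm −10 ml; 56–65 0;
  66–75 +10; 76–90 +20; 91–105 +25; >105 +30 ml.
* `Δ_conc` — ±2 ml per 10 mg I/ml below/above the 350 mg I/ml reference.
* A dilution arm administers half the clamped dose, floored at 20 ml.

Around the calculator the package simulates the pilot study that evaluated
it — truncated-normal cohorts matching the published arm demographics,
per-patient aortic enhancement at five measurement levels, two-reader
five-point visual grading with reader bias, a synthetic CT phantom with
circular-ROI measurement — and analyses it with first-principles statistics
(descriptives, pooled/Welch/paired t-tests at the study's α = 0.025, and the
consistency, average-measures intraclass correlation). It is aimed at
radiology physicists and biostatisticians who want to study or extend
habitus-adapted contrast protocols without access to the original scans.

## Worked example

The calculator's audit trail for the documented extreme patient:

```r
library(aortadose)
calculate_dose(115, 185, 122, 350)
#> Contrast dose plan (literal BSA mode)
#>   patient: 115.0 kg, 185.0 cm, 122 bpm, 350 mg I/ml
#>   BSA:                      2.9549 m^2
#>   base dose (45 ml/m^2):    132.97 ml
#>   heart-rate correction:    +30 ml
#>   concentration correction: +0 ml
#>   raw dose:                 162.97 ml -> 163 ml
#>   clamped dose:             150 ml
#>   final dose:               150 ml
#>   injection: 4 ml/s + 30 ml saline flush
```

The pre-clamp dose of 163 ml (2.95 m² × 45 + 30 for the 122 bpm heart rate)
exceeds the protocol maximum and is clamped to 150 ml. In the dilution arm
the same patient would receive `apply_dilution(...)$final_dose` = 75 ml.

A full simulated study — three arms of 20, dose plans, enhancement, two
readers, analysis — from one seed:

```r
res <- run_pipeline(study_config(seed = 1))
print(res$report)
#> Three-arm study report (student_pooled t-tests, alpha = 0.025)
#>
#> | Variable | standard | calculator | calculator_diluted | standard vs calculator | standard vs calculator_diluted | calculator vs calculator_diluted |
#> |---|---|---|---|---|---|---|
#> | dose | 120.0 ± 0.0 (120.0, 120.0-120.0) | 100.2 ± 18.2 (96.5, 65.0-138.0) | 47.5 ± 7.2 (45.5, 36.0-65.0) | -17% (p < 0.01) | -60% (p < 0.01) | -53% (p < 0.01) |
#> | enhancement | 288.2 ± 64.7 (274.9, 167.7-407.2) | 285.3 ± 48.8 (278.6, 189.8-405.9) | 188.0 ± 58.9 (174.3, 94.6-304.6) | -1% (p 0.87) | -35% (p < 0.01) | -34% (p < 0.01) |
#> | visual_score | 4.5 ± 0.7 (4.8, 3.0-5.0) | 4.7 ± 0.5 (5.0, 3.5-5.0) | 3.7 ± 0.9 (3.5, 2.0-5.0) | +4% (p 0.30) | -19% (p < 0.01) | -22% (p < 0.01) |
#>
#> Inter-observer ICC (consistency, average measures): 0.812
#> Intra-observer ICC (consistency, average measures): 0.974
```

Reading the output: the calculator arm cuts the mean dose by ~17% at
unchanged enhancement (−1%, p 0.87) and unchanged visual quality; the
additional 50% dilution cuts the dose by 60% at the cost of a significant
enhancement and quality drop — the simulated study reproduces the
qualitative pattern of the pilot. `run_pipeline(cfg, out_dir = "run/")`
additionally writes the cohort/dose/enhancement/score CSVs, a JSON and
Markdown report, and an audited run log; outputs are byte-identical for a
fixed seed.

A thin command-line front end over the same functions ships in
`inst/cli/aortadose.R` (`dose`, `cohort`, `simulate`, `analyze`, `report`,
`replicate`, `config --dump`).

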