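# uripp — targeted LC-MS/MS urine purine & pyrimidine assay toolkit

Inborn errors of purine and pyrimidine metabolism (ADSL, ATIC, APRT,
HGPRT, UPB1, UMPS, DPD, DHP, TP, ADA, PNP, and xanthinurias) are rare,
clinically nonspecific, and easy to miss. The diagnostic workhorse is a
targeted LC-MS/MS assay on urine: each metabolite is monitored on a
multiple-reaction-monitoring (MRM) transition, quantified as the response
ratio to an isotopically labeled internal standard (IS), normalized to
urinary creatinine (mmol/mol), compared against age-stratified percentile
cutoffs, and interpreted as a pattern of cutoff exceedances.

`uripp` is the computational layer of such an assay, for laboratory
scientists and method developers. It bundles, as machine-readable data,
a 26-analyte MRM panel (14 purine-side, 12 pyrimidine-side, 11 ISs) with
its transitions, voltages, age-conditional cutoffs, and rule-based
disorder signatures — and implements:

* **sample-prep arithmetic** — creatinine-targeted dilution planning
  (0.25 mM at the first 400 µl stage, 0.20 mM / 5 µM IS in the final
  500 µl) and back-calculation to mmol/mol creatinine;
* **synthetic data** — Gaussian-peak MRM chromatograms on noisy
  baselines, the 10-level calibrator series (0, 1, 2, …, 256 µM),
  age-dependent log-normal reference cohorts, and per-disorder patient
  profiles, all seed-deterministic;
* **peak quantitation** — apex detection at the S/N = 3 rule, trapezoidal
  integration, half-height widths, IS-ratio calibration lines;
* **assay validation** — LOD (S/N = 3), LLOQ (CV < 20%), ULOQ
  (R² > 0.99), precision/recovery CVs, storage stability, and
  chromatographic resolution `Rs = 1.18 (t2 − t1) / (w½,1 + w½,2)` with
  the baseline-resolution bound Rs ≥ 1.5;
* **reference cutoffs** — 99.5th-percentile trimming, 97.5th-percentile
  upper (2.5th lower) cutoffs, and a permutation "quantile ANOVA" over
  the age groups 0–1, 1–3, 3–6, 6–18 y;
* **screening** — fold-over-cutoff computation, ranked signature calls,
  and the allopurinol/orotidine treatment confound.

See `vignettes/assay-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(uripp)

reg <- load_panel()           # the bundled panel
reg
#> <panel_registry>
#>   analytes:            26 ( 14 purine / 12 pyrimidine )
#>   internal standards:  11
#>   transitions:         74
#>   cutoff rules:        32
#>   disorder signatures: 14

plan_urine_prep(2.0)          # a urine with 2.0 mM creatinine
#> <prep_record: urine>
#>   urine 50.0 ul (Cr 2.000 mM) + water 350.0 ul
#>   + IS 100 ul of 25 uM -> 500 ul total
#>   final creatinine 0.2000 mM, final IS 5.00 uM
```

50 µl of urine brings the first 400 µl stage to 0.25 mM creatinine; after
the IS addition the vial holds 0.20 mM creatinine and 5 µM IS — for such
uncapped preps the calibrator-scale readout already *is* mmol/mol
creatinine.

```r
series <- generate_calibrator_series(reg, noise = 0.02, seed = 1,
                                     analytes = "Orotic acid")
calibrate_series(series, reg)[["Orotic acid"]]
#> <calibration: ratio = 0.04027 * conc -0.00294, R^2 = 0.99990, none weights, 9 levels (1-256 uM)>
```

With 2% response noise the 10-level series (blank excluded from the fit)
stays comfortably above the R² > 0.99 linearity criterion.

```r
profile <- generate_patient_profile("ADSL", fold = 5, age = 6,
                                    registry = reg, seed = 7)
round(profile$values[c("SAICAr", "Succinyladenosine")], 2)
#>            SAICAr Succinyladenosine
#>                 4                25
classify(profile, reg)
#> 1. ADSL  (required: SAICAr;Succinyladenosine; max fold 5.0)
```

The ADSL profile carries SAICAr and succinyladenosine at 5× their cutoffs
(0.8 and 5.0 mmol/mol at age 6); the classifier ranks adenylosuccinate
lyase deficiency first. Chromatographic resolution of the panel's
MS/MS-interfering pairs:

```r
critical_pair_resolution(reg)$Rs
#> [1] 1.753 1.753 1.753 1.753     # all >= 1.5: baseline resolved
```

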