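---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uripp` implements the computational layer of a targeted LC-MS/MS urine
assay for inborn errors of purine and pyrimidine metabolism: a
multiple-reaction-monitoring (MRM) panel of 26 analytes quantified against
11 isotopically labeled internal standards, reported in mmol/mol
creatinine, screened against age-stratified percentile cutoffs, and
interpreted by rule-based disorder signatures. This vignette explains the
models and the choices behind them; it states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The assay model

**Sample preparation.** Every sample is brought to a common creatinine
level before injection: a urine aliquot of $0.25 \cdot 400 / c_\mathrm{Cr}$
µl (creatinine $c_\mathrm{Cr}$ in mM) is diluted to 400 µl with water,
targeting 0.25 mM creatinine at the first stage; 100 µl of 25 µM internal
standard (IS) mix is then added. The final 500 µl therefore holds 0.20 mM
creatinine and 5 µM IS. Calibrators and QCs replace the urine/water step
with 100 µl of vial material plus 300 µl synthetic urine (0.333 mM
creatinine), matching the final state to within 1% and diluting the vial
1:5 relative to the pre-preparation calibrator scale on which all readouts
are expressed.

Because the urine volume is inverse in creatinine, the calibrator-scale
readout of an uncapped urine sample *is* its concentration in mmol/mol
creatinine — `back_calculate()` is the identity there. Urines below
0.25 mM creatinine cannot reach the target; they are used neat (400 µl),
flagged `capped`, and corrected explicitly by
$U = \mathrm{readout} \cdot 100 / V_\mathrm{urine}$, $\;\mathrm{result} =
U / c_\mathrm{Cr}$. The source protocol does not state how such samples
were corrected; capping with an explicit dilution-factor correction is this
package's decision (rejecting them would contradict the fact that very
dilute urines were analyzed).

**Quantitation.** Each analyte is measured on a quantifier transition,
confirmed on a qualifier, and quantified as the area ratio to its assigned
IS, read off an ordinary least-squares line fit to the calibrator series
(0, 1, 2, 4, …, 256 µM; the blank is excluded from the fit because with a
log-spaced design the zero level otherwise dominates leverage, and it
serves the limit-of-detection and carryover logic instead). Weighted
(1/x) regression is available behind a flag; whether the original
processing used weighting is unknown, so unweighted is the default and the
round-trip tests pin its correctness.

**Validation statistics.** The definitional thresholds are: LOD at
signal-to-noise 3; LLOQ as the lowest level with replicate CV < 20%; ULOQ
as the top of the range keeping $R^2 > 0.99$; chromatographic resolution
$R_s = 1.18\,(t_2 - t_1)/(w_{0.5,1} + w_{0.5,2})$ with baseline resolution
at $R_s \ge 1.5$; storage stability at CV < 15%. CVs use the $n-1$
denominator throughout because replicate counts are small ($n = 10$ in the
QC design). When a lower level meets the LLOQ criterion but a higher one
fails, the lowest qualifying level *above* the highest failing level is
returned and flagged non-monotone — "the lowest concentration" is
ambiguous in that case.

## The synthetic world

No raw instrument data are available, so every input is generated at desk
scale. The generator states a world once; its defaults are not tuned
against test outcomes.

* **Peaks** are Gaussian with a common sigma of 0.05 min (no peak widths
  are printed in the source; the Gaussian gives closed-form area
  $h\sigma\sqrt{2\pi}$ and width $2.3548\,\sigma$ oracles). Traces cover
  the acquisition window (retention time ± 1.5 min) at 0.005 min steps.
* **Retention times** are synthetic. Only the elution order is published
  (as the numbering of the example chromatograms); the bundled panel
  spaces the 26 analytes over 2–8.5 min preserving that order. Pairs with
  MS/MS interference (shared or 1-Da-adjacent parent masses in the same
  polarity: hypoxanthine/allopurinol, uracil-IS/dihydrouracil,
  deoxyguanosine/inosine, guanosine-IS/orotidine) are given 0.35 min
  gaps so that the stated world satisfies the published baseline-resolution
  bound ($R_s \approx 1.75 \ge 1.5$ at sigma 0.05); remaining gaps are
  ~0.24 min. Labeled internal standards co-elute with their unlabeled
  analytes.
* **Noise** is additive Gaussian on a positive baseline at 4 noise-SDs,
  truncated at zero. The offset exists because a zero-mean truncated
  baseline makes more than half of all points exactly zero and collapses
  any robust noise estimate — real detectors sit on a positive count
  level. Default noise is expressed relative to the 1 µM (Cal02) peak
  height so signal-to-noise claims are controllable.
* **Qualifiers** are generated at a fixed 0.35 ion ratio of the
  quantifier; no ratios are published. The acceptance window of the ion
  ratio check is ±30% relative.
* **The reference cohort** draws ages from the four clinical bins
  ([0,1), [1,3), [3,6), [6,18] years, equal weights, uniform within bins)
  and analyte values from log-normal distributions with median at 1/4 of
  the age-resolved bundled cutoff and $\sigma_{\log} =
  \ln 4 / z_{0.975} \approx 0.707$, so that the true 97.5th percentile
  equals the bundled cutoff and each analyte exceeds it with probability
  0.025. Pseudouridine, the one analyte with a two-sided interval, uses
  the geometric midpoint of its bounds with $\sigma_{\log}$ set so the
  2.5th/97.5th percentiles hit them. Allopurinol, a drug, is identically
  zero in untreated cohorts. These distributions are a fixture choice:
  they reproduce the published cutoff table as their quantiles, not real
  biology. Features of real urine the generator does **not** emulate:
  matrix effects, retention drift, heteroscedastic detector noise,
  correlated metabolite levels, medication other than allopurinol. A green
  test therefore establishes correctness of the computations on the stated
  world, not instrument fidelity.
* **Patient profiles** start from a normal draw and force each signature's
  required markers to `fold ×` their age-resolved upper cutoff (and
  required-low markers to the lower bound divided by the fold).

## Peak integration: numerical choices

The apex is searched on a lightly smoothed signal (11-point moving
average) within ±0.25 min of the expected retention time. Both choices are
defensive: the raw maximum over the ~600 points of an acquisition window
sits near 3 noise-SDs even for a blank, which would defeat the S/N = 3
detection rule, and retention times are stable in a validated assay.
Detection requires the raw apex to clear S/N = 3 *and* the smoothed signal
to agree, so single-sample baseline excursions do not count as peaks.
Baseline and noise are estimated from the outer 10% margins of the window,
the noise as MAD × 1.4826 so a peak shoulder entering a margin does not
inflate it.

Integration bounds walk outward from the apex to the descent at 5% of the
apex and then follow any remaining monotone decay. The strict 5% cut alone
would clip 1.4% of a Gaussian's area and could not meet the 0.5%
closed-form oracle; following the decay integrates a clean peak to the
baseline while noise stops the walk almost immediately beyond the 5%
point. Width at half height interpolates the two half-maximum crossings
linearly.

## Reference cutoffs and the age test

Per metabolite: values strictly above the 99.5th percentile are excluded
(ties retained), the 97.5th percentile of the remainder is the upper
cutoff, and for pseudouridine the 2.5th percentile is the lower cutoff.
All quantiles use linear interpolation between order statistics
(`stats::quantile` type 7); no convention is published, and the test
suite's independent sort-based oracle shares this one.

The published age test is a "one-way ANOVA based on the 97.5th
percentile" without further detail. This package realizes it as a
permutation test: the statistic is the size-weighted between-group
dispersion of the bin-level percentile,
$\sum_b n_b (\hat q_b - \hat q_\mathrm{pooled})^2$, and its null
distribution comes from shuffling ages across samples (199 permutations by
default), which gives exact type-I control under exchangeability — the
property the test suite verifies. A bootstrap variant sits behind
`cutoff_config(method = "bootstrap")`. Quantile-regression with a
rank-based joint test would be the other natural reading; it needs a
quantile-regression package that is not part of this package's dependency
footprint, and the permutation form tests the published statistic most
directly. Samples are put into a canonical order before resampling so the
p-value cannot depend on row order.

After a significant joint test, adjacent bins are merged when their
pairwise permutation test is not significant; "clinically relevant"
merging is modeled as an explicit `clinical_override` map (human judgement
becomes configuration, never hidden logic). Alpha defaults to 0.05
(unstated in the source). At the reference-cohort size ($n = 251$, ~63 per
bin) a single 97.5th percentile carries roughly 12% relative sampling
error, so recovery of generating cutoffs is judged on the panel-wide
median, and only age effects of ≥ 2.5× (the dihydrouracil-like pattern)
are expected to split reliably; the xanthine-like 1.4× effect is below
power at that size.

## Disorder screening

Each analyte is expressed as its fold over the age-resolved upper cutoff.
A signature calls when every required marker exceeds its cutoff
(fold > 1; a value exactly at the cutoff does not flag) and every
required-low marker sits below its lower bound. Calls are ranked by number
of required markers matched, then maximal fold, then code alphabetically;
multiple simultaneous calls are reported, not suppressed. Ages above 18
use the oldest bin with a warning (the cutoffs were built from a 0–18 y
cohort). Allopurinol is a detection-is-abnormal analyte: any found peak
flags it, and when it is detected, elevated orotidine/orotic acid are
annotated as treatment-related and cannot by themselves support an
orotic-aciduria (UMPS) call. XDH deficiency and molybdenum cofactor
deficiency share an identical marker pattern on this panel and are
reported as alternatives by the alphabetical tie-break; distinguishing
them needs sulfite markers outside the assay.

The bundled signature set transcribes the disorders the assay is stated to
detect (ADSL, ATIC, APRT, HGPRT, UPB1, UMPS, DPD, DHP, TP, MoCoD, ADA,
PNP, XDH, PRPPS) as editable JSON configuration, not code — the contestable
biology stays in data.

## Known limitations

* The panel ships 26 analytes; the abstract-level count of 27 likely
  includes creatinine, which is measured on a separate clinical analyzer
  and enters this package only as an input number.
* Published QC table values (CVs, recoveries) are instrument data and are
  shipped as a display-only reference fixture
  (`eqc_reference.tsv`), never recomputed.
* No chromatographic alignment, isotope-interference correction, matrix
  modelling, or vendor raw-file parsing; plain text in and out.
* Generator response factors and retention times are fictional; only their
  structure (order, separation, linearity) carries meaning.
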