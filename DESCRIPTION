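Package: uripp
Title: Targeted LC-MS/MS Urine Purine and Pyrimidine Assay Toolkit
Version: 0.1.0
Authors@R:
    person("uripp", "authors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Computational layer of a targeted multiple-reaction-monitoring
    (MRM) LC-MS/MS urine assay for inborn errors of purine and pyrimidine
    metabolism. Provides a machine-readable panel registry (transitions,
    internal standards, age-stratified cutoffs, disorder signatures),
    synthetic chromatogram and cohort generators, peak integration with
    internal-standard ratio calibration, assay-validation statistics
    (linearity, LOD, LLOQ, ULOQ, precision, recovery, chromatographic
    resolution, stability), percentile-based reference-cutoff estimation
    with age partitioning, creatinine-normalized reporting, and rule-based
    disorder screening with confound flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
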