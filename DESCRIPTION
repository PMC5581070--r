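Package: pethet
Title: FDG-PET Tumor Heterogeneity Metrics and Mutation Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of FDG-PET standardized uptake value (SUV)
    metrics for lung tumors - SUVmax, SUVmean, metabolic tumor volume,
    total lesion glycolysis, metabolic tumor diameter - together with two
    intratumoral heterogeneity scores, the inverse coefficient of
    variation (1/COV) and the area under the cumulative SUV-volume
    histogram (AUC-CSH); gradient-based metabolic tumor delineation from
    a seed point; and the case-control statistical battery relating these
    metrics and clinical covariates to EGFR and KRAS mutation status in
    non-small-cell lung cancer. Includes a synthetic PET phantom and
    cohort simulator with analytic ground truth, so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
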