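Package: renalrules
Title: Rule-Based Staging of Acute and Chronic Kidney Disease from
    Longitudinal Laboratory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A data-driven diagnostic rule engine that assigns staged
    diagnoses of acute kidney injury (AKI, KDIGO stages 1-3), chronic
    kidney disease (CKD, GFR categories 2-5) and acute-on-chronic kidney
    disease from longitudinal serum-creatinine, eGFR and urine
    albumin/creatinine measurements. Detected findings are mapped to
    ICD-10 codes from a configurable catalog, discharge documentation is
    audited by Damerau-Levenshtein fuzzy text search, and prevalence and
    code-conversion statistics are tabulated. A synthetic cohort
    generator with ground-truth labels makes every engine testable
    without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
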