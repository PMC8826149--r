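# renalrules

Rule-based staging of acute and chronic kidney disease from longitudinal
laboratory data.

Hospitals hold years of timestamped serum-creatinine and eGFR
measurements, yet the diagnoses that depend on them — acute kidney
injury (AKI), chronic kidney disease (CKD) and their combination,
acute-on-chronic kidney disease — are still often assigned by hand, and
often imprecisely (the catch-all ICD code N19, *kidney failure,
unspecified*, instead of a staged N17.x/N18.x diagnosis). `renalrules`
implements the KDIGO diagnostic criteria as an auditable rule engine for
retrospective and desk-scale use: it ingests patient, encounter and
laboratory tables, stages every inpatient case, emits ICD codes from a
configurable catalog map, cross-checks discharge letters by fuzzy text
search, and tabulates prevalence and code-conversion statistics. A
synthetic cohort generator with exact ground-truth labels makes the
whole pipeline testable without access to clinical data.

Intended users: medical-controlling and clinical-data-science teams who
need reproducible electronic phenotyping of kidney disease from routine
labs, and methodologists who want a reference implementation of the
KDIGO staging arithmetic.

## The diagnostic model

**AKI** is staged from ordered pairs of serum-creatinine values
(SCr, µmol/L). For a pair (first, second) with ratio r = second/first
measured Δt hours apart:

| Stage | Criterion | Rule |
|---|---|---|
| 3 | `threshold_crossing_7d` | first < 353.6 µmol/L (4 mg/dL) < second, Δt ≤ 168 h |
| 3 | `ratio_7d` | r ≥ 3.0, Δt ≤ 168 h |
| 2 | `ratio_7d` | 2.0 ≤ r < 3.0, Δt ≤ 168 h |
| 1 | `ratio_7d` | 1.5 ≤ r < 2.0, Δt ≤ 168 h |
| 1 | `absolute_48h` | second − first ≥ 26.52 µmol/L (0.3 mg/dL), Δt ≤ 48 h |

All pairs from 7 days before admission until discharge are mapped; the
reported finding is the **highest stage with the shortest interval**.
The baseline is min(lowest in-hospital SCr, mean of outpatient SCr in
the 90 days before admission); an outpatient-mean baseline also enters
the pair mapping as a virtual earlier value. Urine-output (oliguria)
criteria are deliberately not implemented.

**CKD** is staged from eGFR series (CKD-EPI 2009 creatinine equation,
mL/min/1.73 m²): a GFR category g2–g5 is assigned when *all* values in
a window spanning more than 91 days lie under 90/60/30/15 respectively,
with at least one confirming value in the 90 days before the index
date. The reported finding is the **highest stage with the longest
window**. A kidney-transplant history or a moderately/severely
increased urinary albumin-to-creatinine ratio (ACR ≥ 3 mg/g, categories
A2/A3) establishes CKD of unspecified stage when no eGFR window
qualifies; stage 1 is never assigned (no limiting eGFR exists for it).

A case with both findings is flagged **acute-on-chronic** and carries
both code families (by default N17.91–93, N18.2–5, N18.9; the map is
data, not logic). Discharge letters are audited with a restricted
Damerau–Levenshtein fuzzy search for renal terms (*kreatinin*,
*niereninsuffizienz*, *nierenversagen*, *AKI*, *CKD*, *eGFR*, *KDIGO*,
and exact staging patterns such as `G3A2`).

## Worked example

```r
library(renalrules)

ser <- tibble::tibble(
  value = c(82, 80, 130, 250, 110),
  ts = as.POSIXct("2019-03-01 08:00", tz = "UTC") + c(0, 24, 48, 96, 168) * 3600
)
enc <- list(case_id = "C1", patient_id = "P1",
            admit_ts = as.POSIXct("2019-03-01 06:00", tz = "UTC"),
            discharge_ts = as.POSIXct("2019-03-12 10:00", tz = "UTC"))
(finding <- classify_aki(enc, ser))
#> <aki_finding> stage 3 (ratio_7d): 80.0 -> 250.0 µmol/L over 72.0 h
finding$baseline
#> <kd_baseline> 80.0 µmol/L (inpatient_min; 5 inpatient, 0 outpatient values)
```

The engine found the 80 → 250 µmol/L pair (a 212% rise within 7 days,
stage 3) rather than any of the lesser rises, and reports the shortest
qualifying interval. Adding a chronic component and coding the case:

```r
egfr <- tibble::tibble(
  value = c(48, 52, 45),
  ts = as.POSIXct(c("2018-11-20", "2019-01-15", "2019-03-05"), tz = "UTC"))
ckd <- classify_ckd(list(transplant_history = FALSE), egfr,
                    index_date = enc$discharge_ts)
#> <ckd_finding> stage 3 over 105 days (3 values, max eGFR 52.0)
combine_diagnoses(finding, ckd, enc, map = default_icd_map())
#> <diagnosis_set> case C1: AKI 3 + CKD 3 [generated] codes: N17.93;N18.3
```

All three eGFR values sit under 60 for more than 91 days, so the case
is acute-on-chronic and both family codes are emitted. The same logic
scales to a whole cohort — here the bundled generator, whose planted
stages the engines must recover exactly:

```r
g <- generate_cohort(synth_config(n_patients = 200), seed = 1)
g$cohort
#> <kd_cohort> 200 patients, 200 encounters, 2924 lab measurements, 200 reports
res <- run_pipeline(g$cohort, out_dir = "out")
# comparing res$findings against g$truth: 100% AKI and CKD stage recovery
```

`run_pipeline()` writes `findings.csv`, per-term hit tables,
`case_audit.csv`, `prevalence.csv`, `conversion.csv`, `mutations.log`
and a run manifest. A command-line wrapper with `run`, `synth`, `audit`
and `report` subcommands ships in `inst/scripts/renalrules-cli.R`:

```sh
Rscript inst/scripts/renalrules-cli.R synth --seed 5 --out demo
Rscript inst/scripts/renalrules-cli.R run --patients demo/patients.csv \
  --encounters demo/encounters.csv --labs demo/labs.csv \
  --reports demo/reports.csv --out demo_run
```

## Scope and limitations

The engine is retrospective and desk-scale: it does not speak HL7,
does not alert in real time, and does not model reimbursement. Oliguria-based AKI criteria and
CKD stage 1 are excluded by design. The synthetic generator emulates
measurement cadences and staging margins, not physiology — see the
methods vignette for what passing tests do and do not establish.
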