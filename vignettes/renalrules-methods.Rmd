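---
title: "Methods: KDIGO-based staging of kidney disease from laboratory time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KDIGO-based staging of kidney disease from laboratory time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalrules)
```

`renalrules` turns the KDIGO diagnostic criteria for acute kidney
injury (AKI) and chronic kidney disease (CKD) into a deterministic,
auditable rule engine over timestamped laboratory tables. This vignette
is the package's own account of that model: the procedure, its
assumptions, the tunable constants, the numerical conventions, the
design choices that were genuinely open, and the limits of what the
test suite shows.

## Data model and time arithmetic

Three tables carry everything the engines need: patients (birth date,
sex, transplant history), encounters (case ID with admission and
discharge timestamps) and laboratory measurements (analyte, value,
unit, timestamp, care setting). Timestamps are parsed as ISO-8601 with
explicit offsets and converted to a single UTC timeline; every window
rule — 48 hours, 7 days, 91 days, 90 days, one year — is then exact
arithmetic on fractional hours. Serum creatinine is normalised to
µmol/L at ingest (factor 88.4 from mg/dL, the unique factor consistent
with the clinical threshold pairs 0.3 mg/dL = 26.52 µmol/L and
4 mg/dL = 353.6 µmol/L); eGFR stays in mL/min/1.73 m². How a mixed-unit
laboratory feed was reconciled upstream is unknowable from the data, so
ingest-time normalisation is this package's own convention.

Two ingest rules keep the pipeline auditable. Duplicate
(patient, analyte, timestamp) rows keep the last occurrence and return
the rest with a reason, so `count(in) == count(kept) + count(rejected)`
always holds. The inpatient/outpatient label is taken from the input
column when present and inferred from encounter overlap only when
absent, because the label matters for the baseline but cannot be
reconstructed reliably from admission windows alone (outpatient visits
during a stay, transfers).

## AKI staging

All creatinine values from 7 days before admission until discharge are
paired; each ordered pair (first, second, Δt) is staged:

* stage 3 if the pair crosses 353.6 µmol/L from strictly below to
  strictly above within 7 days (`threshold_crossing_7d`);
* stage 3/2/1 if the ratio second/first falls in [3, ∞), [2, 3),
  [1.5, 2) within 7 days (`ratio_7d`);
* stage 1 if the absolute rise is ≥ 26.52 µmol/L within 48 hours
  (`absolute_48h`).

The prose bands of the clinical definitions overlap at their edges
("50%–100%", "100%–200%"); half-open intervals with the upper stage
winning at the boundary are the only consistent reading, and the "200%
or more" wording fixes ≥ at 3.0. Window bounds are inclusive ("within
48 hours / 7 days"). Decreases are never staged; only the highest stage
is reported, ties broken by the shortest interval between the mapped
values, then by the earliest later timestamp, so identical inputs give
identical output. An encounter with no creatinine measurement is
classified as not having AKI rather than missing.

### Baseline

The baseline is min(lowest in-hospital value, arithmetic mean of
outpatient values in the 90 days before admission) — either source may
reflect premorbid kidney function, and taking the lower errs toward
sensitivity. How the baseline enters pair mapping is not fixed by the
clinical definitions, so the package makes the mechanism explicit and
configurable (`aki.baseline_as_virtual_pair`): when the baseline
derives from the outpatient mean, it is injected as a virtual earlier
value against every in-window measurement under the 7-day presumption
(an acute rise against a recent outpatient baseline is presumed to have
occurred within 7 days). Two deliberate consequences: a virtual pair's
interval is pinned to the 168-hour bound, so it can never satisfy the
48-hour absolute criterion (whose timing is genuinely unknown) and it
always loses a shortest-interval tie to a real pair. When the inpatient
minimum is the baseline it already exists in the series and needs no
injection. Admission-day values are a known baseline
candidate in the literature but miss community-acquired episodes that
improve in hospital; they are not implemented here.

## CKD staging

Windows are all timestamp pairs of the eGFR series spanning strictly
more than 91 days; "at least three months" and ">91 days" are
harmonised to the single 2184-hour constant to avoid two near-identical
bounds. A window is staged by the smallest threshold in
{15, 30, 60, 90} strictly bounding **all** its values (15 → stage 5,
…, 90 → stage 2); any value ≥ 90 disqualifies it. Per window the
min/mean/max are computed and retained for audit even though only the
maximum participates in staging. The reported finding is the highest
stage with the longest span (then earliest start, for determinism).

The series lookback is 365 days before the index date — a diagnosis
rests on criteria fulfilled within the previous year — and a finding
must be confirmed by at least one value consistent with its stage
within 90 days before the index date, so that a historical window
cannot diagnose a patient whose recent values have recovered. Both
are calendar-free day counts for determinism.
The recency check could plausibly gate every finding or only code
emission; it is applied to every finding here and is switchable
(`ckd.require_recency`). The index date is the
encounter's discharge when classifying per case — diagnoses are
validated at discharge — else the latest measurement.

When no eGFR window qualifies, a transplant history or an
albumin-to-creatinine ratio in category A2/A3 within the lookback
still establishes CKD, with stage *unspecified* (coded N18.9): the
GFR categories are defined on eGFR only, so ACR evidence is kept
parallel and never modifies a stage. Stage 1 is never assigned — KDIGO
defines no limiting eGFR for it, so a purely numeric engine cannot
detect it.

### eGFR and ACR arithmetic

eGFR rows may arrive precomputed from the laboratory (pass-through) or
be computed from creatinine with the 2009 CKD-EPI equation
(`ckd_epi_egfr()`); both routes are supported because it is unknowable
which one produced a given feed. The race coefficient sits behind an
explicit flag defaulting to `FALSE`; the 2021 race-free refit and
cystatin-C equations are out of scope. The ACR is urinary albumin
(mg/L) over urinary creatinine (g/L) in mg/g — the standard KDIGO
marker; an occasionally-seen variant with creatinine in the numerator
is a transcription slip and is deliberately not implemented.
Category boundaries: A1 below 3 mg/g, A2 from 3 to 30 inclusive
("between 3 and 30"), A3 above 30 — the one place boundaries are
closed rather than half-open, following the wording. Albumin and
creatinine must come from one sample or at most 30 days apart; urine
creatinine in mmol/L converts via the molar mass 113.12 g/mol.

## Coding, validation and reporting

A case's AKI and CKD findings combine into one diagnosis set;
acute-on-chronic is defined as both present. The detection date — the
link between a finding and its inpatient case — is the date of the
latest contributing measurement clamped into the stay; no standard
fixes this convention, so the package documents its own. Code emission is a pure lookup in a
catalog map shipped as data (`inst/extdata/icd_map.yaml`): AKI stages →
N17.91/92/93, CKD stages → N18.2–5, unspecified chronic → N18.9,
unspecified any → N19. Catalog-year variants are alternative files, not
code. The engine itself never emits N19: codes exist iff a finding
exists, and an unspecified code never accompanies a specific one of the
same family.

Clinician validation is modelled as a single accept/reject transition
per generated diagnosis set; rejection deletes the codes, and every
transition appends to a mutation log from which the full code history
replays. The reporting module reproduces the two evaluation-table
shapes: prevalence of reduced eGFR and of coded kidney disease per
period, and the conversion of generated unspecified codes into specific
families under validation. Every printed percentage equals
`proportion(n, N)` of the two counts printed beside it, with half-up
rounding at two decimals — the convention of commercial medical
statistics. The three conversion outcomes need not be mutually
exclusive per case; cases
converting to both families are counted once per family and surfaced
in a separate combined-count column so the table stays auditable.

## Text audit

Discharge letters are scanned for a German-language term list
(*kreatinin*, *niereninsuffizienz*, *nierenversagen*, *aki*, *ckd*,
*egfr*, *kdigo*) plus the exact staging pattern `G[1-5]A[1-3]`. Text
is case-folded and tokenized on Unicode non-letter boundaries — umlauts
preserved, no stemming — and a token matches a term when its restricted
Damerau–Levenshtein distance (optimal string alignment: insertions,
deletions, substitutions, adjacent transpositions, no re-editing after
a transposition) is within the term's budget. The restricted variant is
what production fuzzy-search engines implement behind the tilde
operator, and the budgets follow that convention: 1 edit for terms up
to 8 characters, 2 for longer ones, exact match for patterns. No
universal cutoff exists, so these defaults are configuration
(`inst/extdata/terms.yaml`), not claims.

One mathematical caveat is worth stating: the restricted distance is
not a metric — `d("ca","ab") + d("ab","abc") < d("ca","abc")` — so the
package also provides the unrestricted Damerau–Levenshtein variant
(`dl_distance(..., method = "dl")`), which satisfies the triangle
inequality; the property suite tests symmetry, identity and
oracle-agreement on the restricted variant and the triangle inequality
on the unrestricted one. With a budget of 0 the search reduces to exact
token matching. Hits aggregate per case into boolean term flags joined
with the case's coded family (N17 / N18 / N17+N18 / N19 / none), from
which documentation proportions per family are computed. Negation
detection, ranking and morphological analysis are out of scope.

## Synthetic cohort generator

The generator is first-class, tested code: it emits the same CSV
schemas the ingest reads, plus a truth table, so every engine is
exercisable without clinical data. Composition defaults (40% healthy,
25% AKI split evenly over the five stage/criterion profiles, 25% CKD
over stages 2–5 plus transplant-history and albuminuria-only patients,
10% acute-on-chronic covering all criterion-stage combinations) are
chosen so that every rule path occurs dozens of times in a 200-patient
cohort — a composition far richer in disease than any real hospital
year, by design, since the generator's purpose is coverage, not
epidemiology.

Trajectories are piecewise constant with event jumps, not kinetic
models: the engines consume discrete measurements, and trajectory
realism is a non-goal. Episodes are constructed with margin from every
band edge so that each labelled case satisfies exactly its stage and
criterion and no higher stage: ratio episodes use multipliers 1.7, 2.5
and 3.5 (mid-band); the absolute-criterion episode adds 30 µmol/L to
the observed plateau maximum while the plateau (85–100 µmol/L) keeps
the ratio under 1.5; the threshold-crossing episode jumps a 330 µmol/L
plateau to 380. CKD profiles place values mid-category (75/45/22/10)
from 200 days before admission to one day after it, guaranteeing a
>91-day span and a confirming value in the recency window.
Measurement noise is a uniform coefficient of variation; above 0.05
the absolute-criterion margin could be crossed by a stationary series,
so such configurations are rejected as infeasible rather than
generating mislabelled truth. A single `set.seed(seed)` at entry
drives every draw; equal seeds give byte-identical output files.

Planted report terms are perturbed, with configurable probability, by
exactly one adjacent transposition or substitution — distance 1 from
the canonical spelling, never equal to it, each term appearing once per
report — so fuzzy search at budget ≥ 1 must find them and exact search
must not.

What passing recovery tests show, and what they do not: they establish
that the engines implement the staging arithmetic exactly on data whose
truth is known by construction, including at the band edges. They do
not establish clinical validity on real data, where baselines are
missing, sampling is irregular, units are dirty and documentation is
incomplete — the properties the ingest validation and the audit tables
are designed to surface, not solve.

## Numerical conventions and problem sizes

Percentages round half-up at two decimals with a 1e-9 epsilon against
binary representation error. Creatinine conversion uses 88.4 exactly;
invertibility holds to 1e-9 relative tolerance. CKD-EPI is continuous
at the sex-specific knot to 1e-9 relative tolerance. Tie-breaks
(shortest interval then earliest timestamp for AKI; longest span then
earliest start for CKD) make every selection deterministic. The
property suites run 1000 random series per engine against brute-force
oracles (series of up to 8 values — small enough for exhaustive pair
and window enumeration, large enough that every selection rule is
exercised), 10,000 random string pairs against a memoized-recursion
distance oracle, and a 200-patient recovery cohort; these sizes keep
the default test run within a few minutes on one CPU while leaving
each property's failure modes densely sampled.

## Known limitations

* Urine-output (oliguria) AKI criteria are excluded; staging relies on
  creatinine alone.
* CKD stage 1 cannot be detected numerically and is never assigned.
* The baseline definition (minimum of in-hospital minimum and 90-day
  outpatient mean) is one of several in circulation; minimum-based
  baselines are known to inflate AKI incidence relative to admission
  values, a sensitivity-favouring choice that limits comparability
  across systems.
* Dialysis initiation, transplant coding beyond the history flag,
  progression modelling and reimbursement grouping are out of scope.
* The ICD map ships as a single default catalog; real deployments must
  supply their catalog-year files.
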