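# Default stage-to-ICD-code map. Catalog-year variants are alternative
# copies of this file; pass one to `renalrules-cli run --icd-map`.
catalog_id: default-n17-n18
aki_stage_codes:
  "1": N17.91
  "2": N17.92
  "3": N17.93
ckd_stage_codes:
  "2": N18.2
  "3": N18.3
  "4": N18.4
  "5": N18.5
unspecified_chronic: N18.9
unspecified_any: N19
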