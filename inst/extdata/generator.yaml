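# Default synthetic-cohort composition: 40% healthy, 25% AKI episodes
# (five stage/criterion profiles), 25% CKD (stages 2-5, transplant
# history, albuminuria-only), 10% acute-on-chronic combinations.
n_patients: 200
frac_healthy: 0.40
frac_aki: 0.25
frac_ckd: 0.25
frac_acute_on_chronic: 0.10
noise: 0
misspelling_rate: 0.3
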