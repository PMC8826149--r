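# Default renal search terms for the discharge-letter audit.
# max_edits follows the tilde-operator convention: 1 edit for terms up
# to 8 characters, 2 for longer terms; patterns match exactly.
- term: aki
  max_edits: 1
- term: ckd
  max_edits: 1
- term: egfr
  max_edits: 1
- term: kdigo
  max_edits: 1
- term: kreatinin
  max_edits: 2
- term: niereninsuffizienz
  max_edits: 2
- term: nierenversagen
  max_edits: 2
- term: "G[1-5]A[1-3]"
  max_edits: 0
  is_pattern: true
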