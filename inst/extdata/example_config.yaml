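synthetic:
  'n': 4137.0
  seed: 20.0
subgroups:
- diabetes
- dyslipidemia
imputation:
  enabled: yes
  m: 5.0
dop_draws: 1000000.0
seed: 20.0
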