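{
  "proportions": [0.33, 0.511, 0.159],
  "rr": 2.64,
  "baseline_prevalence": 0.005,
  "shift": 0.10
}
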