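{
  "seed": 7,
  "simulate": {
    "n_instruments": {"childhood": 120, "adult": 150},
    "true_effects": {"childhood": 0.6931472, "adult": 0.0},
    "exposure_correlation": 0.3,
    "frac_palindromic": 0.1,
    "frac_allele_swapped": 0.2,
    "n_cohort": 2000,
    "grs_effect": 0.033,
    "seed": 7
  },
  "n_boot": 200,
  "focal_exposure": "childhood",
  "analyses": {
    "univariable": true,
    "multivariable": true,
    "reverse": true,
    "intervention": true
  },
  "intervention": {
    "proportions": [0.33, 0.511, 0.159],
    "rr": 2.64,
    "baseline_prevalence": 0.005,
    "shift": 0.10
  }
}
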