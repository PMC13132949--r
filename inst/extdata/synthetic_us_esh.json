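{
  "type": "gaussian_poly",
  "name": "synthetic_us_esh",
  "note": "SYNTHETIC stand-in for the original (all-weights) US reference used by the ESH guideline; highest thresholds of the three. Not the published coefficients; see synthetic_us_aap.json.",
  "coef": {
    "sbp": {
      "female": {"alpha": 107.5, "beta": [1.5, 0.02], "gamma": [0.9], "sigma": 9.4},
      "male":   {"alpha": 107.8, "beta": [1.6, 0.02], "gamma": [0.9], "sigma": 9.6}
    },
    "dbp": {
      "female": {"alpha": 68.0, "beta": [0.5], "gamma": [0.35], "sigma": 5.8},
      "male":   {"alpha": 67.6, "beta": [0.5], "gamma": [0.35], "sigma": 5.9}
    }
  }
}
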