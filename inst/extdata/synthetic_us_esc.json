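{
  "type": "gaussian_poly",
  "name": "synthetic_us_esc",
  "note": "SYNTHETIC stand-in for the weight-modified US reference as adopted by the ESC guideline. Not the published coefficients; see synthetic_us_aap.json.",
  "coef": {
    "sbp": {
      "female": {"alpha": 106.0, "beta": [1.45, 0.02], "gamma": [0.8], "sigma": 8.7},
      "male":   {"alpha": 106.3, "beta": [1.55, 0.02], "gamma": [0.8], "sigma": 8.9}
    },
    "dbp": {
      "female": {"alpha": 66.6, "beta": [0.48], "gamma": [0.3], "sigma": 5.6},
      "male":   {"alpha": 66.2, "beta": [0.48], "gamma": [0.3], "sigma": 5.7}
    }
  }
}
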