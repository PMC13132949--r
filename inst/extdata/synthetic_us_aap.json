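{
  "type": "gaussian_poly",
  "name": "synthetic_us_aap",
  "note": "SYNTHETIC stand-in for the weight-modified US auscultatory reference used by the AAP guideline. The published coefficient sets are third-party appendix data and are NOT reproduced here; these coefficients merely mimic the functional form (polynomial in centered age and height z-score, Gaussian residual) with thresholds slightly above the Danish oscillometric reference.",
  "coef": {
    "sbp": {
      "female": {"alpha": 105.3, "beta": [1.45, 0.02], "gamma": [0.8], "sigma": 8.4},
      "male":   {"alpha": 105.6, "beta": [1.55, 0.02], "gamma": [0.8], "sigma": 8.6}
    },
    "dbp": {
      "female": {"alpha": 66.2, "beta": [0.48], "gamma": [0.3], "sigma": 5.4},
      "male":   {"alpha": 65.8, "beta": [0.48], "gamma": [0.3], "sigma": 5.5}
    }
  }
}
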