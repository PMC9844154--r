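{
  "name": "predicted-TILes two-feature GLSZM model",
  "version": "1.0",
  "intercept_known": false,
  "coefficients": {
    "glszm_gray_level_variance": 1.71e-03,
    "glszm_large_area_low_gray_level_emphasis": -2.48e-05
  },
  "response": "TILes (fraction of analyzable TME area with inflamed or immune-excluded grids)",
  "notes": [
    "Coefficients are treated as original-feature-scale values; the intercept was not published, so scores are defined up to an additive constant.",
    "Median grouping, rank correlation and Cox regression on the score are invariant to that constant.",
    "Reported TILes log2 fold changes between feature-high and -low groups: 0.732 (gray level variance), -0.754 (large area low gray level emphasis)."
  ]
}
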