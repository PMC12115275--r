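[
  {"formulation": "F13", "hausner_ratio": 1.36, "mean_hardness_n": 62.5, "friability_pct": 0.89, "disintegration_s": 50,  "diameter_mm": 5},
  {"formulation": "F14", "hausner_ratio": 1.32, "mean_hardness_n": 24.8, "friability_pct": 0.38, "disintegration_s": 45,  "diameter_mm": 5},
  {"formulation": "F15", "hausner_ratio": 1.19, "mean_hardness_n": 27.6, "friability_pct": 0.89, "disintegration_s": 103, "diameter_mm": 5},
  {"formulation": "F16", "hausner_ratio": 1.23, "mean_hardness_n": 37.4, "friability_pct": 1.00, "disintegration_s": 420, "diameter_mm": 5}
]
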