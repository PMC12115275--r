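[
  {"formulation": "F1",  "target_r": 5.0, "mean_weight_mg": 187.6, "mean_hardness_n": 147.7, "diameter_mm": 9},
  {"formulation": "F2",  "target_r": 5.0, "mean_weight_mg": 172.9, "mean_hardness_n": 159.9, "diameter_mm": 9},
  {"formulation": "F3",  "target_r": 5.0, "mean_weight_mg": 697.6, "mean_hardness_n": 331.8, "diameter_mm": 13},
  {"formulation": "F4",  "target_r": 5.0, "mean_weight_mg": 250.0, "mean_hardness_n": 230.5, "diameter_mm": 9},
  {"formulation": "F5",  "target_r": 4.5, "mean_weight_mg": 160.9, "mean_hardness_n": 121.9, "diameter_mm": 8},
  {"formulation": "F6",  "target_r": 4.5, "mean_weight_mg": 112.0, "mean_hardness_n": 113.4, "diameter_mm": 8},
  {"formulation": "F7",  "target_r": 4.5, "mean_weight_mg": 172.7, "mean_hardness_n": 48.0,  "diameter_mm": 8},
  {"formulation": "F8",  "target_r": 4.5, "mean_weight_mg": 131.3, "mean_hardness_n": 78.3,  "diameter_mm": 8},
  {"formulation": "F9",  "target_r": 4.0, "mean_weight_mg": 83.0,  "mean_hardness_n": 77.0,  "diameter_mm": 6},
  {"formulation": "F10", "target_r": 4.0, "mean_weight_mg": 82.7,  "mean_hardness_n": 73.2,  "diameter_mm": 6},
  {"formulation": "F11", "target_r": 4.0, "mean_weight_mg": 101.5, "mean_hardness_n": 55.4,  "diameter_mm": 6},
  {"formulation": "F12", "target_r": 4.0, "mean_weight_mg": 88.4,  "mean_hardness_n": 21.2,  "diameter_mm": 6},
  {"formulation": "F13", "target_r": 3.5, "mean_weight_mg": 67.0,  "mean_hardness_n": 62.5,  "diameter_mm": 5},
  {"formulation": "F14", "target_r": 3.5, "mean_weight_mg": 62.8,  "mean_hardness_n": 24.8,  "diameter_mm": 5},
  {"formulation": "F15", "target_r": 3.5, "mean_weight_mg": 69.9,  "mean_hardness_n": 27.6,  "diameter_mm": 5},
  {"formulation": "F16", "target_r": 3.5, "mean_weight_mg": 68.1,  "mean_hardness_n": 37.4,  "diameter_mm": 5}
]
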