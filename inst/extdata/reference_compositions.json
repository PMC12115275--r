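[
  {"formulation": "F1",  "target_r": 5.0, "excipient": "L-HPC LH11",   "api_pct": 26.70, "excipient_pct": 69.80, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F2",  "target_r": 5.0, "excipient": "L-HPC NBD022", "api_pct": 28.97, "excipient_pct": 67.53, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F3",  "target_r": 5.0, "excipient": "PARTECK ODT",  "api_pct": 7.23,  "excipient_pct": 89.27, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F4",  "target_r": 5.0, "excipient": "PROSOLV ODT",  "api_pct": 20.59, "excipient_pct": 75.91, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F5",  "target_r": 4.5, "excipient": "L-HPC LH11",   "api_pct": 43.48, "excipient_pct": 53.02, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F6",  "target_r": 4.5, "excipient": "L-HPC NBD022", "api_pct": 45.20, "excipient_pct": 51.30, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F7",  "target_r": 4.5, "excipient": "PARTECK ODT",  "api_pct": 28.69, "excipient_pct": 67.81, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F8",  "target_r": 4.5, "excipient": "PROSOLV ODT",  "api_pct": 38.84, "excipient_pct": 57.66, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F9",  "target_r": 4.0, "excipient": "L-HPC LH11",   "api_pct": 60.26, "excipient_pct": 36.24, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F10", "target_r": 4.0, "excipient": "L-HPC NBD022", "api_pct": 61.44, "excipient_pct": 35.06, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F11", "target_r": 4.0, "excipient": "PARTECK ODT",  "api_pct": 50.15, "excipient_pct": 46.35, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F12", "target_r": 4.0, "excipient": "PROSOLV ODT",  "api_pct": 57.08, "excipient_pct": 39.42, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F13", "target_r": 3.5, "excipient": "L-HPC LH11",   "api_pct": 77.04, "excipient_pct": 19.46, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F14", "target_r": 3.5, "excipient": "L-HPC NBD022", "api_pct": 77.67, "excipient_pct": 18.83, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F15", "target_r": 3.5, "excipient": "PARTECK ODT",  "api_pct": 71.61, "excipient_pct": 24.89, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00},
  {"formulation": "F16", "target_r": 3.5, "excipient": "PROSOLV ODT",  "api_pct": 75.33, "excipient_pct": 21.17, "talc_pct": 2.36, "colloidal_silicon_dioxide_pct": 0.14, "magnesium_stearate_pct": 1.00}
]
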