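{
  "F13": {
    "excipient": "L-HPC LH11",
    "radii": {
      "Da": 4.84, "Dc": 6.59, "Ie": 4.58, "IC": 5.31, "Icd": 10.00,
      "IH": 8.19, "alpha": 3.30, "t_flow": 3.67, "HR": 7.63, "H": 8.24,
      "Pf": 2.69, "Itheta": 1.85
    },
    "reported_incidences": {
      "dimensions": 5.72, "compressibility": 6.63, "flowability": 5.05,
      "lubricity_stability": 7.94, "lubricity_dosage": 2.27
    },
    "reported_igc": 5.31
  },
  "F14": {
    "excipient": "L-HPC NBD022",
    "radii": {
      "Da": 4.73, "Dc": 6.49, "Ie": 4.78, "IC": 5.42, "Icd": 10.00,
      "IH": 8.14, "alpha": 3.76, "t_flow": 0.00, "HR": 7.77, "H": 8.55,
      "Pf": 0.62, "Itheta": 1.95
    },
    "reported_incidences": {
      "dimensions": 5.61, "compressibility": 6.73, "flowability": 3.97,
      "lubricity_stability": 8.16, "lubricity_dosage": 1.28
    },
    "reported_igc": 4.94
  }
}
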