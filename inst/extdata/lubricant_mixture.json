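{
  "talc": 2.36,
  "colloidal_silicon_dioxide": 0.14,
  "magnesium_stearate": 1.00
}
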