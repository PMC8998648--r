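{
  "grid_spacing": 0.05,
  "J0": {
    "trans": {"LOD": -0.26, "LDD": -0.25},
    "cis": {"LOD": -0.2, "LDD": -0.4}
  },
  "l_R_policy": "fixed",
  "l_R": 8
}
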