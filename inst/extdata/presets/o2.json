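{
  "experiment": "o2",
  "input_reaction": "O2in",
  "from": 0, "to": 100, "step": 1,
  "objectives": ["minApo", "maxDeg"],
  "pin_mode": "pin",
  "augment_objective": true,
  "description": "Increase of O2; the O2 input reaction is included in the optimization function with weight 1 in the primary sense"
}
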