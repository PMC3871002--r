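{
  "experiment": "tyrosine",
  "input_reaction": "TYRin",
  "from": 0, "to": 100, "step": 1,
  "objectives": ["minApo", "maxDeg"],
  "pin_mode": "pin",
  "augment_objective": false,
  "description": "Increased dopamine synthesis via the tyrosine precursor input"
}
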