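{
  "experiment": "atp",
  "input_reaction": "ATPin",
  "from": 0, "to": 1000, "step": 1,
  "objectives": ["minApo", "maxDeg"],
  "pin_mode": "pin",
  "augment_objective": false,
  "description": "Increase of ATP production via the ATPase input"
}
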