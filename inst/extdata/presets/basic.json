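{
  "experiment": "basic",
  "objectives": ["maxApo", "minApo", "maxDeg", "minDeg"],
  "description": "Normal nerve cell: four-objective suite over the functional groups"
}
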