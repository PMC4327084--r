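{
  "scales": { "T0": 39.0, "t1": 0.65, "t2": 0.5 },
  "z0a": 0.02
}
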