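{
  "kappa_e": 0.026,
  "kappa_i": 0.5,
  "T0": 39.0,
  "square": { "a": 0.04, "d": 2e-05, "rho": 1e-04, "U": 0.6555 },
  "ring": { "z0": 0.0008, "S": 2e-08, "R": 4.0, "U": 0.6444 }
}
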