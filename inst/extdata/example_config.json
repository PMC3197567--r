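{
  "dimensionless": {
    "lambda1": 0,
    "lambda2": 50,
    "lambda3": 0.5
  },
  "solver": {
    "dx": 0.002,
    "dt": 0.005
  }
}
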