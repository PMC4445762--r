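{
  "alpha": 0.34,
  "alpha_beta_ratio": 10
}
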