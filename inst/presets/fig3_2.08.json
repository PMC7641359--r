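{
  "dV_d": -2.08,
  "dV_f": 2.08
}
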