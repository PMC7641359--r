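{
  "dV_d": -3.85,
  "dV_f": 0
}
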