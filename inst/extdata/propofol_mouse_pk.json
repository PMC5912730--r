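{
  "k10": 0.07,
  "k12": 1.55,
  "k13": 0.22,
  "k21": 2.71,
  "k31": 0.04,
  "s_inf": 0.35
}
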