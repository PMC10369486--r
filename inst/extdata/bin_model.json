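{
  "p": 65,
  "t": 180,
  "m": -65,
  "halfwidth": 30
}
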