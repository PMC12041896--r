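{
  "loci": ["A", "B"],
  "alleles": {
    "A": ["a1", "a2"],
    "B": ["b1", "b2"]
  },
  "fitness": {
    "a1,b1": 1,
    "a1,b2": 0.25,
    "a2,b1": 0.25,
    "a2,b2": 2
  }
}
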