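{
  "endocrine_society": { "deficient_below": 50, "sufficient_above": 75 },
  "iom_50": { "deficient_below": 50, "sufficient_above": 50 },
  "iom_30": { "deficient_below": 30, "sufficient_above": 30 }
}
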