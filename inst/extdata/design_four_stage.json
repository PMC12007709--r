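{
  "label": "four-stage, continue probs 0.8 0.5 0.5 0.5",
  "stages": [
    {"sensitive_prob": 0.2},
    {"sensitive_prob": 0.5},
    {"sensitive_prob": 0.5},
    {"sensitive_prob": 0.5}
  ],
  "Q": 0.1
}
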