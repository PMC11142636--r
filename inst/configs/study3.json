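{
  "study": 3,
  "condition": "blocked",
  "n_instances": 58,
  "seed": 1
}
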