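{
  "standards": [
    {"true_bp": 2991, "imaged_bp": 2721, "imaged_bp_se": 106},
    {"true_bp": 7029, "imaged_bp": 6456, "imaged_bp_se": 82}
  ]
}
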