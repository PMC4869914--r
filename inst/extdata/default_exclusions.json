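{
  "excluded_regions": [
    {"start": 16129, "end": 16430, "note": "simple repeat region"}
  ]
}
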