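{
  "specs": ["ctd_like.json", "monarch_like.json", "mychem_like.json"],
  "hierarchy": "hierarchy.txt",
  "normalizer": "normalizer.json",
  "cooccurrence": "cooccurrence.json",
  "associations": "data"
}
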