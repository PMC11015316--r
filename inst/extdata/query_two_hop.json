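{
  "message": {
    "query_graph": {
      "nodes": {
        "n0": {"ids": ["MONDO:0005148"], "categories": ["Disease"]},
        "n1": {"categories": ["Gene"]},
        "n2": {"categories": ["ChemicalEntity"]}
      },
      "edges": {
        "e0": {"subject": "n0", "object": "n1"},
        "e1": {"subject": "n1", "object": "n2"}
      }
    }
  }
}
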