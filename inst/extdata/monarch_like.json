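{
  "info": {"title": "Monarch-like API", "version": "1.0"},
  "servers": [{"url": "https://monarch.example.org"}],
  "paths": {
    "/bioentity/disease": {
      "x-kg-operations": [
        {
          "op_id": "op_monarch_disease_gene",
          "input_category": "Disease",
          "input_prefix": "MONDO",
          "predicate": "condition_associated_with_gene",
          "output_category": "Gene",
          "output_prefix": "NCBIGene",
          "method": "GET",
          "request_template": "ids={inputs}",
          "response_id_path": "associations[].object.id"
        }
      ]
    }
  }
}
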