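{
  "info": {"title": "CTD-like API", "version": "1.0"},
  "servers": [{"url": "https://ctd.example.org"}],
  "paths": {
    "/disease_genes": {
      "x-kg-operations": [
        {
          "op_id": "op_ctd_disease_gene",
          "input_category": "Disease",
          "input_prefix": "MONDO",
          "predicate": "condition_associated_with_gene",
          "output_category": "Gene",
          "output_prefix": "NCBIGene",
          "method": "GET",
          "request_template": "q={inputs}",
          "response_id_path": "hits[].id",
          "max_batch": 3
        }
      ]
    }
  }
}
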