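{
  "info": {"title": "MyChem-like API", "version": "1.0"},
  "servers": [{"url": "https://mychem.example.org"}],
  "paths": {
    "/query": {
      "x-kg-operations": [
        {
          "op_id": "op_mychem_gene_chem",
          "input_category": "Gene",
          "input_prefix": "NCBIGene",
          "predicate": "interacts_with",
          "output_category": "ChemicalEntity",
          "output_prefix": "CHEBI",
          "method": "POST",
          "request_template": "{\"q\": \"{inputs}\"}",
          "response_id_path": "data.results[].output_id"
        }
      ]
    }
  }
}
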