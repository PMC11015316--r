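[
  {"canonical": "MONDO:0005148", "category": "Disease", "label": "type 2 diabetes mellitus", "equivalents": ["DOID:9352"]},
  {"canonical": "MONDO:0005015", "category": "Disease", "label": "diabetes mellitus", "equivalents": []},
  {"canonical": "NCBIGene:7157", "category": "Gene", "label": "TP53", "equivalents": ["ENSEMBL:ENSG00000141510"]},
  {"canonical": "NCBIGene:1017", "category": "Gene", "label": "CDK2", "equivalents": ["ENSEMBL:ENSG00000123374"]},
  {"canonical": "NCBIGene:5468", "category": "Gene", "label": "PPARG", "equivalents": []},
  {"canonical": "NCBIGene:3630", "category": "Gene", "label": "INS", "equivalents": []},
  {"canonical": "CHEBI:15365", "category": "SmallMolecule", "label": "acetylsalicylic acid", "equivalents": ["DRUGBANK:DB00945"]},
  {"canonical": "CHEBI:45783", "category": "SmallMolecule", "label": "imatinib", "equivalents": []},
  {"canonical": "CHEBI:17234", "category": "SmallMolecule", "label": "glucose", "equivalents": []}
]
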