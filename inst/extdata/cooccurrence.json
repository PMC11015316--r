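{
  "N": 1000,
  "terms": {
    "MONDO:0005148": 100,
    "MONDO:0005015": 80,
    "NCBIGene:7157": 50,
    "NCBIGene:1017": 30,
    "NCBIGene:5468": 20,
    "NCBIGene:3630": 40,
    "CHEBI:15365": 60,
    "CHEBI:45783": 25,
    "CHEBI:17234": 15
  },
  "pairs": [
    ["MONDO:0005148", "NCBIGene:7157", 25],
    ["MONDO:0005148", "NCBIGene:1017", 10],
    ["MONDO:0005148", "NCBIGene:5468", 2],
    ["MONDO:0005015", "NCBIGene:3630", 30],
    ["NCBIGene:7157", "CHEBI:15365", 20],
    ["NCBIGene:1017", "CHEBI:45783", 5]
  ]
}
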