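input	output
NCBIGene:7157	CHEBI:15365
NCBIGene:1017	CHEBI:45783
NCBIGene:5468	CHEBI:17234
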