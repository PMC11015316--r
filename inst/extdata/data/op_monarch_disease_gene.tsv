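input	output
MONDO:0005148	NCBIGene:7157
MONDO:0005148	NCBIGene:5468
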