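NamedThing	-
Disease	NamedThing
Gene	NamedThing
ChemicalEntity	NamedThing
PhenotypicFeature	NamedThing
SmallMolecule	ChemicalEntity
#predicates
related_to	-
associated_with	related_to
affects	related_to
interacts_with	related_to
condition_associated_with_gene	associated_with
gene_associated_with_condition	associated_with
treats	affects
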