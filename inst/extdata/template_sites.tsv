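# Structural-template ion-coordination residues.
# LeuT_2A65: Aquifex aeolicus leucine transporter, PDB 2A65 chain numbering.
# SERT_NP_001036: human serotonin transporter, NP_001036.1 numbering.
template_id	site	pos	residue
LeuT_2A65	Na1	22	A
LeuT_2A65	Na1	24	G
LeuT_2A65	Na1	27	N
LeuT_2A65	Na1	254	T
LeuT_2A65	Na2	20	G
LeuT_2A65	Na2	23	V
LeuT_2A65	Na2	351	A
LeuT_2A65	Na2	354	T
LeuT_2A65	Na2	355	S
SERT_NP_001036	Cl	121	Y
SERT_NP_001036	Cl	336	S
SERT_NP_001036	Cl	368	N
SERT_NP_001036	Cl	372	S
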