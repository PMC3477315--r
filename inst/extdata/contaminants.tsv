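# Default contaminant table: biotin-dependent carboxylases (bind streptavidin
# beads via their covalent biotin cofactor) and common bead-binding background.
# Synthetic/bundled reference list; extend via filter_criteria().
accession	description	class
PC_HUMAN	Pyruvate carboxylase	biotin_carboxylase
MCCA_HUMAN	Methylcrotonoyl-CoA carboxylase subunit alpha	biotin_carboxylase
MCCB_HUMAN	Methylcrotonoyl-CoA carboxylase subunit beta	biotin_carboxylase
PCCA_HUMAN	Propionyl-CoA carboxylase alpha chain	biotin_carboxylase
PCCB_HUMAN	Propionyl-CoA carboxylase beta chain	biotin_carboxylase
ACACA_HUMAN	Acetyl-CoA carboxylase 1	biotin_carboxylase
ACACB_HUMAN	Acetyl-CoA carboxylase 2	biotin_carboxylase
K2C1_HUMAN	Keratin, type II cytoskeletal 1	bead_background
K1C10_HUMAN	Keratin, type I cytoskeletal 10	bead_background
ALBU_HUMAN	Serum albumin	bead_background
TRYP_PIG	Trypsin	bead_background
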