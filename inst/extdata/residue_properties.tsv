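property	residues
hydrophobic	ACFGHIKLMTVWY
aliphatic	ILV
aromatic	FHWY
polar	CDEHKNQRSTWY
positive	HKR
negative	DE
charged	DEHKR
small	ACDGNPSTV
tiny	AGS
proline	P
buried	ACFGILMVWY
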