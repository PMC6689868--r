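name	smarts	rationale
aryl_propyl_tertiary_amine	c[CX4][CX4][CX4][NX3]([CX4])[CX4]	Basic tertiary amine three rotatable bonds from an aromatic ring; the canonical cation-pi hERG pharmacophore shape (synthetic surrogate alert).
basic_secondary_amine_linker	c[CX4][CX4][NX3;H1][CX4]	Protonatable secondary amine on a short benzylic linker; captures flexible basic centres near lipophilic aromatics.
aryl_piperidine	c[NX3]1[CX4][CX4][CX4][CX4][CX4]1	N-aryl piperidine; rigidified basic nitrogen adjacent to an aromatic system.
aryl_piperazine	[NX3]1[CX4][CX4][NX3][CX4][CX4]1	Piperazine; doubly basic saturated diamine ring frequent in channel blockers.
haloaryl_basic_amine	[F,Cl]c1ccc(cc1)[CX4][CX4][NX3]	Halogenated aromatic with a proximal basic amine; lipophilicity-guarded variant of the basic-amine motif.
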