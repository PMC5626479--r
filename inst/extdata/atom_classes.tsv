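# Mapping from (residue, PDB atom name) to united-atom LJ class, v1.
# Backbone atoms use residue "*" (any); GLY CA is overridden explicitly.
resid	atom	atom_class
*	N	NH1E
*	CA	CH1E
*	C	C
*	O	O
*	OXT	OC
GLY	CA	CH2E
ALA	CB	CH3E
ARG	CB	CH2E
ARG	CG	CH2E
ARG	CD	CH2E
ARG	NE	NH1E
ARG	CZ	C
ARG	NH1	NH2E
ARG	NH2	NH2E
ASN	CB	CH2E
ASN	CG	C
ASN	OD1	O
ASN	ND2	NH2E
ASP	CB	CH2E
ASP	CG	C
ASP	OD1	OC
ASP	OD2	OC
CYS	CB	CH2E
CYS	SG	SH1E
GLN	CB	CH2E
GLN	CG	CH2E
GLN	CD	C
GLN	OE1	O
GLN	NE2	NH2E
GLU	CB	CH2E
GLU	CG	CH2E
GLU	CD	C
GLU	OE1	OC
GLU	OE2	OC
HIS	CB	CH2E
HIS	CG	CAr
HIS	ND1	NH1E
HIS	CD2	CR1E
HIS	CE1	CR1E
HIS	NE2	N
ILE	CB	CH1E
ILE	CG1	CH2E
ILE	CG2	CH3E
ILE	CD1	CH3E
ILE	CD	CH3E
LEU	CB	CH2E
LEU	CG	CH1E
LEU	CD1	CH3E
LEU	CD2	CH3E
LYS	CB	CH2E
LYS	CG	CH2E
LYS	CD	CH2E
LYS	CE	CH2E
LYS	NZ	NH3E
MET	CB	CH2E
MET	CG	CH2E
MET	SD	S
MET	CE	CH3E
PHE	CB	CH2E
PHE	CG	CAr
PHE	CD1	CR1E
PHE	CD2	CR1E
PHE	CE1	CR1E
PHE	CE2	CR1E
PHE	CZ	CR1E
PRO	CB	CH2E
PRO	CG	CH2E
PRO	CD	CH2E
PRO	N	N
SER	CB	CH2E
SER	OG	OH1E
THR	CB	CH1E
THR	OG1	OH1E
THR	CG2	CH3E
TRP	CB	CH2E
TRP	CG	CAr
TRP	CD1	CR1E
TRP	CD2	CAr
TRP	NE1	NH1E
TRP	CE2	CAr
TRP	CE3	CR1E
TRP	CZ2	CR1E
TRP	CZ3	CR1E
TRP	CH2	CR1E
TYR	CB	CH2E
TYR	CG	CAr
TYR	CD1	CR1E
TYR	CD2	CR1E
TYR	CE1	CR1E
TYR	CE2	CR1E
TYR	CZ	CAr
TYR	OH	OH1E
VAL	CB	CH1E
VAL	CG1	CH3E
VAL	CG2	CH3E
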