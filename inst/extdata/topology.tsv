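# Side-chain heavy-atom internal-coordinate topology, v1.
# One row per side-chain atom beyond CB, in build order. Each atom is placed
# by NeRF from (ggparent, gparent, parent) with the given bond length (A),
# bond angle (deg, gparent-parent-atom) and torsion (deg,
# ggparent-gparent-parent-atom). Torsion entries may reference chi angles
# ("chi1", "chi2+180", ...). CB is placed tetrahedrally from N/CA/C and is
# not listed. Ring closures are idealized (planar rings built atom by atom).
resid	atom	parent	gparent	ggparent	bond	angle	torsion
ARG	CG	CB	CA	N	1.52	114.0	chi1
ARG	CD	CG	CB	CA	1.52	111.5	chi2
ARG	NE	CD	CG	CB	1.46	112.0	chi3
ARG	CZ	NE	CD	CG	1.33	124.5	chi4
ARG	NH1	CZ	NE	CD	1.33	120.0	0
ARG	NH2	CZ	NE	CD	1.33	120.0	180
ASN	CG	CB	CA	N	1.52	112.7	chi1
ASN	OD1	CG	CB	CA	1.23	120.8	chi2
ASN	ND2	CG	CB	CA	1.33	116.5	chi2+180
ASP	CG	CB	CA	N	1.52	112.7	chi1
ASP	OD1	CG	CB	CA	1.25	118.5	chi2
ASP	OD2	CG	CB	CA	1.25	118.5	chi2+180
CYS	SG	CB	CA	N	1.81	114.0	chi1
GLN	CG	CB	CA	N	1.52	114.0	chi1
GLN	CD	CG	CB	CA	1.52	112.7	chi2
GLN	OE1	CD	CG	CB	1.23	120.8	chi3
GLN	NE2	CD	CG	CB	1.33	116.5	chi3+180
GLU	CG	CB	CA	N	1.52	114.0	chi1
GLU	CD	CG	CB	CA	1.52	112.7	chi2
GLU	OE1	CD	CG	CB	1.25	118.5	chi3
GLU	OE2	CD	CG	CB	1.25	118.5	chi3+180
HIS	CG	CB	CA	N	1.50	113.8	chi1
HIS	ND1	CG	CB	CA	1.38	122.7	chi2
HIS	CD2	CG	CB	CA	1.36	129.7	chi2+180
HIS	CE1	ND1	CG	CB	1.32	109.3	180
HIS	NE2	CD2	CG	CB	1.37	107.2	180
ILE	CG1	CB	CA	N	1.53	110.4	chi1
ILE	CG2	CB	CA	N	1.53	110.5	chi1-120
ILE	CD1	CG1	CB	CA	1.53	113.8	chi2
LEU	CG	CB	CA	N	1.53	116.3	chi1
LEU	CD1	CG	CB	CA	1.53	110.7	chi2
LEU	CD2	CG	CB	CA	1.53	110.7	chi2+120
LYS	CG	CB	CA	N	1.52	114.0	chi1
LYS	CD	CG	CB	CA	1.52	111.5	chi2
LYS	CE	CD	CG	CB	1.52	111.5	chi3
LYS	NZ	CE	CD	CG	1.49	112.0	chi4
MET	CG	CB	CA	N	1.52	114.0	chi1
MET	SD	CG	CB	CA	1.80	112.7	chi2
MET	CE	SD	CG	CB	1.79	100.8	chi3
PHE	CG	CB	CA	N	1.50	113.8	chi1
PHE	CD1	CG	CB	CA	1.39	120.7	chi2
PHE	CD2	CG	CB	CA	1.39	120.7	chi2+180
PHE	CE1	CD1	CG	CB	1.39	120.7	180
PHE	CE2	CD2	CG	CB	1.39	120.7	180
PHE	CZ	CE1	CD1	CG	1.39	120.0	0
PRO	CG	CB	CA	N	1.50	104.5	chi1
PRO	CD	CG	CB	CA	1.51	106.1	chi2
SER	OG	CB	CA	N	1.42	110.8	chi1
THR	OG1	CB	CA	N	1.43	109.6	chi1
THR	CG2	CB	CA	N	1.53	110.5	chi1-120
TRP	CG	CB	CA	N	1.50	113.8	chi1
TRP	CD1	CG	CB	CA	1.37	126.9	chi2
TRP	CD2	CG	CB	CA	1.43	126.7	chi2+180
TRP	NE1	CD1	CG	CB	1.38	110.2	180
TRP	CE2	CD2	CG	CB	1.41	107.2	180
TRP	CE3	CD2	CG	CB	1.40	133.9	0
TRP	CZ2	CE2	CD2	CG	1.40	122.4	180
TRP	CZ3	CE3	CD2	CG	1.39	118.6	180
TRP	CH2	CZ2	CE2	CD2	1.37	117.5	0
TYR	CG	CB	CA	N	1.50	113.8	chi1
TYR	CD1	CG	CB	CA	1.39	120.7	chi2
TYR	CD2	CG	CB	CA	1.39	120.7	chi2+180
TYR	CE1	CD1	CG	CB	1.39	120.7	180
TYR	CE2	CD2	CG	CB	1.39	120.7	180
TYR	CZ	CE1	CD1	CG	1.39	120.0	0
TYR	OH	CZ	CE1	CD1	1.38	119.9	180
VAL	CG1	CB	CA	N	1.53	110.5	chi1
VAL	CG2	CB	CA	N	1.53	110.5	chi1+120
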