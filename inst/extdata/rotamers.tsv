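# Compact backbone-independent rotamer library, v1.
# Canonical gauche-/trans/gauche+ chi combinations with approximate
# literature frequencies (relative weights; normalized per residue type at
# load). Chi angles in degrees; empty fields mean the residue has fewer
# rotatable side-chain bonds. ALA and GLY have a single chi-less rotamer.
resid	chi1	chi2	chi3	chi4	weight
ALA					1.00
GLY					1.00
ARG	-60	180	180	180	0.35
ARG	180	180	180	180	0.30
ARG	-60	180	-60	180	0.20
ARG	60	180	180	180	0.15
ASN	-60	-60			0.30
ASN	-60	60			0.20
ASN	180	-60			0.25
ASN	180	60			0.25
ASP	-60	-30			0.40
ASP	180	-30			0.35
ASP	60	-30			0.25
CYS	-60				0.50
CYS	180				0.30
CYS	60				0.20
GLN	-60	180	0		0.30
GLN	-60	180	90		0.25
GLN	180	180	0		0.25
GLN	180	60	0		0.20
GLU	-60	180	0		0.35
GLU	180	180	0		0.30
GLU	-60	-60	0		0.20
GLU	60	180	0		0.15
HIS	-60	90			0.30
HIS	-60	-90			0.25
HIS	180	90			0.20
HIS	180	-90			0.15
HIS	60	90			0.10
ILE	-60	180			0.60
ILE	-60	-60			0.15
ILE	180	180			0.15
ILE	60	180			0.10
LEU	-60	180			0.55
LEU	180	60			0.30
LEU	180	180			0.10
LEU	-60	60			0.05
LYS	-60	180	180	180	0.40
LYS	180	180	180	180	0.35
LYS	-60	-60	180	180	0.15
LYS	60	180	180	180	0.10
MET	-60	180	180		0.25
MET	-60	180	-60		0.20
MET	-60	-60	-60		0.20
MET	180	180	180		0.20
MET	180	180	60		0.15
PHE	-60	90			0.50
PHE	180	90			0.35
PHE	60	90			0.15
PRO	27	-34			0.50
PRO	-27	34			0.50
SER	60				0.45
SER	-60				0.30
SER	180				0.25
THR	60				0.45
THR	-60				0.40
THR	180				0.15
TRP	-60	90			0.30
TRP	-60	-90			0.30
TRP	180	-90			0.20
TRP	180	90			0.10
TRP	60	-90			0.10
TYR	-60	90			0.50
TYR	180	90			0.35
TYR	60	90			0.15
VAL	180				0.60
VAL	-60				0.25
VAL	60				0.15
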