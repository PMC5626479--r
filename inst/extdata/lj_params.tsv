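# United heavy-atom 12-6 Lennard-Jones parameters, v1.
# sigma in Angstrom, epsilon in kcal/mol. Values follow common united-atom
# force-field magnitudes (OPLS-UA-like); combined by Lorentz-Berthelot rules.
atom_class	sigma	epsilon
C	3.75	0.105
CH1E	3.85	0.080
CH2E	3.905	0.118
CH3E	3.905	0.175
CR1E	3.75	0.110
CAr	3.55	0.070
N	3.25	0.170
NH1E	3.25	0.170
NH2E	3.30	0.170
NH3E	3.25	0.170
O	2.96	0.210
OC	2.96	0.210
OH1E	3.07	0.170
S	3.55	0.250
SH1E	3.55	0.250
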