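# Reduced curated structural-alert set for QED alert counting (common
# reactive / undesirable functionality). name<TAB>SMARTS, one per line.
nitro_group	[N+](=O)[O-]
aldehyde	[CX3H1](=O)[#6]
acyl_halide	[CX3](=O)[F,Cl,Br,I]
michael_acceptor_enone	C=CC(=O)[#6,#8,#7]
epoxide	C1OC1
aziridine	C1NC1
azo_group	N=N
hydrazine	[NX3][NX3]
thiol	[#6][SX2H]
alkyl_halide_reactive	[CH2X4][Cl,Br,I]
isocyanate	N=C=O
peroxide	[OX2][OX2]
sulfonyl_halide	S(=O)(=O)[F,Cl,Br,I]
anhydride	C(=O)OC(=O)
imine_of_aldehyde	C=[N!R]
phosphorus_halide	P[F,Cl,Br,I]
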