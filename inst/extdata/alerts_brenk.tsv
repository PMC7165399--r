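# BRENK structural-alert catalog: substructures flagged as reactive, toxic or
# pharmacokinetically unfavourable.
# Source: Brenk R et al. (2008) ChemMedChem 3:435-444 (doi:10.1002/cmdc.200700139).
# Format: SMARTS<TAB>label, one alert per line.
C(=O)O[C,H1].C(=O)O[C,H1].C(=O)O[C,H1]	>_2_ester_groups
n1c([F,Cl,Br,I])cccc1	2-halo_pyridine
C(=O)[Cl,Br,I,F]	acid_halide
C=[C!r]O	acyclic_C=C-O
N#CC(=O)	acyl_cyanide
C(=O)N[NH2]	acyl_hydrazine
[CH1](=O)	aldehyde
[R0;D2][R0;D2][R0;D2][R0;D2]	Aliphatic_long_chain
[CX4][Cl,Br,I]	alkyl_halide
c1nnnn1C=O	amidotetrazole
c1cc([NH2])ccc1	aniline
[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1	azepane
N#N	Azo_group
[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1	azocane
[cR2]1[cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2][cR2]1[cR2]2[cR2][cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2]2	benzidine
[C,c](=O)[CX4,CR0X3,O][C,c](=O)	beta-keto/anhydride
C12C(NC(N1)=O)CSC2	biotin_analogue
[C+,c+,C-,c-]	Carbo_cation/anion
c1c([OH])c([OH,NH2,NH])ccc1	catechol
[O+,o+,S+,s+]	charged_oxygen_or_sulfur_atoms
C1(=[O,N])C=CC(=[O,N])C=C1	chinone_1
C1(=[O,N])C(=[O,N])C=CC=C1	chinone_2
C=[C!r]C#N	conjugated_nitrile_group
[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]	crown_ether
c1ccc2c(c1)ccc(=O)o2	cumarine
N[CH2]C#N	cyanamide
[N,O,S]C#N	cyanate_/aminonitrile_/thiocyanate
N#CC[OH]	cyanohydrins
[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2]1	cycloheptane_1
[CR2]1[CR2][CR2]cc[CR2][CR2]1	cycloheptane_2
[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2][CR2]1	cyclooctane_1
[CR2]1[CR2][CR2]cc[CR2][CR2][CR2]1	cyclooctane_2
[cR2]1[cR2]c([N+0X3R0,nX3R0])c([N+0X3R0,nX3R0])[cR2][cR2]1	diaminobenzene_1
[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2]c([N+0X3R0,nX3R0])[cR2]1	diaminobenzene_2
[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2][cR2]c1([N+0X3R0,nX3R0])	diaminobenzene_3
[N!R]=[N!R]	diazo_group
[C,c](=O)[C,c](=O)	diketo_group
SS	disulphide
[CX2R0][NX3R0]	enamine
C(=O)Onnn	ester_of_HOBT
C1(=O)OCC1	four_member_lactones
c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]	halogenated_ring_1
c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]	halogenated_ring_2
[Hg,Fe,As,Sb,Zn,Se,se,Te,B,Si]	heavy_metal
[NX3R0,NX4R0,OR0,SX2R0][CX4][NX3R0,NX4R0,OR0,SX2R0]	het-C-het_not_in_ring
C1NC(=O)NC(=O)1	hydantoin
[OH]c1ccc([OH,NH2,NH])cc1	hydroquinone
C(=O)N[OH]	hydroxamic_acid
C=[N!R]	imine_1
N=[CR0][N,n,O,S]	imine_2
I	iodine
N=C=O	isocyanate
[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]=[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]	isolated_alkene
C=C=O	ketene
S1C=CSC1=S	methylidene-1,3-dithiole
C=!@CC=[O,S]	Michael_acceptor_1
[$([CH]),$(CC)]#CC(=O)[C,c]	Michael_acceptor_2
[$([CH]),$(CC)]#CS(=O)(=O)[C,c]	Michael_acceptor_3
C=C(C=O)C=O	Michael_acceptor_4
[$([CH]),$(CC)]#CC(=O)O[C,c]	Michael_acceptor_5
[NX2,nX3][OX1]	N_oxide
s1c(S)nnc1NC=O	N-acyl-2-amino-5-mercapto-1,3,4-_thiadiazole
NC[F,Cl,Br,I]	N-C-halo
[NX3,NX4][F,Cl,Br,I]	N-halo
n[OH]	N-hydroxyl_pyridine
[#7]-N=O	N-nitroso
[C,c]=N[OH]	oxime_1
[C,c]=NOC=O	oxime_2
[OR0,NR0][OR0,NR0]	Oxygen-nitrogen_single_bond
[CX4](F)(F)[CX4](F)F	Perfluorinated_chain
OO	peroxide
c1ccccc1OC(=O)[#6]	phenol_ester
c1ccccc1OC(=O)O	phenyl_carbonate
P A	phosphor
[cR,CR]~C(=O)NC(=O)~[cR,CR]	phthalimide
a1aa2a3a(a1)A=AA=A3=AA=A2	Polycyclic_aromatic_hydrocarbon_1
a21aa3a(aa1aaaa2)aaaa3	Polycyclic_aromatic_hydrocarbon_2
a31a(a2a(aa1)aaaa2)aaaa3	Polycyclic_aromatic_hydrocarbon_3
[CR0]=[CR0][CR0]=[CR0]	polyene
[s,S,c,C,n,N,o,O]~[nX3+,NX3+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]	quaternary_nitrogen_1
[s,S,c,C,n,N,o,O]~[n+,N+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]	quaternary_nitrogen_2
[*]=[N+]=[*]	quaternary_nitrogen_3
O1CCCCC1OC2CCC3CCCCC3C2	saponine_derivative
[Si][F,Cl,Br,I]	silicon_halogen
c1ccccc1C=Cc2ccccc2	stilbene
[SX3](=O)[O-,OH]	sulfinic_acid
[C,c]S(=O)(=O)O[C,c]	Sulfonic_acid_1
S(=O)(=O)[O-,OH]	Sulfonic_acid_2
S(=O)(=O)C#N	sulfonyl_cyanide
[SX2]O	sulfur_oxygen_single_bond
OS(=O)(=O)[O-]	sulphate
[SX2H0][N]	sulphur_nitrogen_single_bond
c12ccccc1(SC(S)=N2)	Thiobenzothiazole_1
c12ccccc1(SC(=S)N2)	thiobenzothiazole_2
[C,c]=S	Thiocarbonyl_group
SC=O	thioester
[S-]	thiol_1
[SH]	thiol_2
*1[O,S,N]*1	Three-membered_heterocycle
OS(=O)(=O)(C(F)(F)(F))	triflate
[SiR0,CR0](c1ccccc1)(c2ccccc2)(c3ccccc3)	triphenyl_methyl-silyl
N=[N+]=[N-]	Azido_group
N[NH2]	hydrazine
[N+](=O)[O-]	nitro_group
C#C	triple_bond
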