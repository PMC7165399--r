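# Bundled complementary reactant set: small molecules (< 250 Da) covering
# the functional groups the default reaction sets consume. A desk-scale
# counterpart of vendor-derived complementary libraries; users supply
# their own SMI file for production runs.
CCO ethanol
CCCO propan-1-ol
CC(C)O propan-2-ol
OCCc1ccccc1 phenethyl_alcohol
OCC1CCCCC1 cyclohexylmethanol
CC(=O)O acetic_acid
CCC(=O)O propanoic_acid
OC(=O)C1CCCC1 cyclopentanecarboxylic_acid
OC(=O)c1ccccc1 benzoic_acid
OC(=O)Cc1ccccc1 phenylacetic_acid
NCC ethylamine
NCCC propylamine
NCC(C)C isobutylamine
NCc1ccccc1 benzylamine
NC1CCCCC1 cyclohexylamine
NCCc1ccccc1 phenethylamine
CNC dimethylamine
CNCC N-methylethylamine
C1CCNC1 pyrrolidine
C1CCNCC1 piperidine
C1COCCN1 morpholine
CCCN=[N+]=[N-] propyl_azide
N=[N+]=[N-]Cc1ccccc1 benzyl_azide
CCN=[N+]=[N-] ethyl_azide
C#CC propyne
C#CCO propargyl_alcohol
C#CCN propargylamine
C#CCC but-1-yne
C#Cc1ccccc1 phenylacetylene
CCBr bromoethane
CCCBr 1-bromopropane
BrCc1ccccc1 benzyl_bromide
CC(C)Br 2-bromopropane
ICC iodoethane
Brc1ccccc1 bromobenzene
Brc1ccc(C)cc1 4-bromotoluene
Ic1ccccc1 iodobenzene
Fc1ccc(cc1)[N+](=O)[O-] 4-fluoronitrobenzene
SCC ethanethiol
SCCC propanethiol
SCc1ccccc1 benzyl_mercaptan
Oc1ccccc1 phenol
Oc1ccc(C)cc1 p-cresol
CC=O acetaldehyde
CCC=O propanal
O=Cc1ccccc1 benzaldehyde
O=CC1CCCCC1 cyclohexanecarbaldehyde
CC(=O)C acetone
CC(=O)CC butanone
CC(=O)c1ccccc1 acetophenone
CC1CO1 propylene_oxide
C1CO1 ethylene_oxide
CCN=C=O ethyl_isocyanate
CCN=C=S ethyl_isothiocyanate
OB(O)c1ccccc1 phenylboronic_acid
OB(O)c1ccc(C)cc1 4-tolylboronic_acid
NN hydrazine
NO hydroxylamine
CS(=O)(=O)Cl methanesulfonyl_chloride
O=S(=O)(Cl)c1ccccc1 benzenesulfonyl_chloride
CC(=O)Cl acetyl_chloride
ClC(=O)OCC ethyl_chloroformate
CC(=O)OC(C)=O acetic_anhydride
CC(=O)CBr bromoacetone
N#CCC#N malononitrile
CCC#N propionitrile
NC(=S)c1ccccc1 thiobenzamide
CC(=O)CC(C)=O acetylacetone
Nc1ccccc1N benzene-1,2-diamine
Oc1ccccc1N 2-aminophenol
Sc1ccccc1N 2-aminothiophenol
CC(=O)NN acethydrazide
C=CC(C)=O methyl_vinyl_ketone
C=CCC but-1-ene
CC(=O)S thioacetic_acid
CS(=O)(=O)N=[N+]=[N-] mesyl_azide
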