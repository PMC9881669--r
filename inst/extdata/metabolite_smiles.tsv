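name	smiles
glycine	NCC(=O)O
alanine	CC(N)C(=O)O
serine	OCC(N)C(=O)O
cysteine	SCC(N)C(=O)O
threonine	CC(O)C(N)C(=O)O
valine	CC(C)C(N)C(=O)O
leucine	CC(C)CC(N)C(=O)O
asparagine	NC(=O)CC(N)C(=O)O
aspartic_acid	OC(=O)CC(N)C(=O)O
glutamine	NC(=O)CCC(N)C(=O)O
glutamic_acid	OC(=O)CCC(N)C(=O)O
lysine	NCCCCC(N)C(=O)O
arginine	NC(=N)NCCCC(N)C(=O)O
histidine	OC(=O)C(N)Cc1c[nH]cn1
phenylalanine	OC(=O)C(N)Cc1ccccc1
tyrosine	OC(=O)C(N)Cc1ccc(O)cc1
tryptophan	OC(=O)C(N)Cc1c[nH]c2ccccc12
methionine	CSCCC(N)C(=O)O
proline	OC(=O)C1CCCN1
ornithine	NCCCC(N)C(=O)O
citrulline	NC(=O)NCCCC(N)C(=O)O
homocysteine	SCCC(N)C(=O)O
homoserine	OCCC(N)C(=O)O
sarcosine	CNCC(=O)O
lactic_acid	CC(O)C(=O)O
pyruvic_acid	CC(=O)C(=O)O
acetic_acid	CC(=O)O
propionic_acid	CCC(=O)O
butyric_acid	CCCC(=O)O
valeric_acid	CCCCC(=O)O
succinic_acid	OC(=O)CCC(=O)O
fumaric_acid	OC(=O)C=CC(=O)O
malic_acid	OC(=O)CC(O)C(=O)O
citric_acid	OC(=O)CC(O)(CC(=O)O)C(=O)O
alpha_ketoglutaric_acid	OC(=O)CCC(=O)C(=O)O
oxaloacetic_acid	OC(=O)CC(=O)C(=O)O
glutaric_acid	OC(=O)CCCC(=O)O
adipic_acid	OC(=O)CCCCC(=O)O
pimelic_acid	OC(=O)CCCCCC(=O)O
suberic_acid	OC(=O)CCCCCCC(=O)O
azelaic_acid	OC(=O)CCCCCCCC(=O)O
malonic_acid	OC(=O)CC(=O)O
oxalic_acid	OC(=O)C(=O)O
glycolic_acid	OCC(=O)O
tartaric_acid	OC(=O)C(O)C(O)C(=O)O
levulinic_acid	CC(=O)CCC(=O)O
itaconic_acid	OC(=O)CC(=C)C(=O)O
sorbic_acid	CC=CC=CC(=O)O
benzoic_acid	OC(=O)c1ccccc1
salicylic_acid	OC(=O)c1ccccc1O
anthranilic_acid	Nc1ccccc1C(=O)O
hippuric_acid	OC(=O)CNC(=O)c1ccccc1
cinnamic_acid	OC(=O)C=Cc1ccccc1
p_coumaric_acid	OC(=O)C=Cc1ccc(O)cc1
caffeic_acid	OC(=O)C=Cc1ccc(O)c(O)c1
ferulic_acid	COc1cc(C=CC(=O)O)ccc1O
vanillic_acid	COc1cc(C(=O)O)ccc1O
gallic_acid	OC(=O)c1cc(O)c(O)c(O)c1
protocatechuic_acid	OC(=O)c1ccc(O)c(O)c1
quinic_acid	OC1CC(O)(C(=O)O)CC(O)C1O
shikimic_acid	OC1CC(=CC(O)C1O)C(=O)O
glucose	OCC1OC(O)C(O)C(O)C1O
ribose	OCC1OC(O)C(O)C1O
sucrose	OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O
glycerol	OCC(O)CO
erythritol	OCC(O)C(O)CO
sorbitol	OCC(O)C(O)C(O)C(O)CO
myo_inositol	OC1C(O)C(O)C(O)C(O)C1O
n_acetylglucosamine	CC(=O)NC1C(O)OC(CO)C(O)C1O
glucose_6_phosphate	OC1OC(COP(=O)(O)O)C(O)C(O)C1O
glycerol_3_phosphate	OCC(O)COP(=O)(O)O
phosphoenolpyruvate	OC(=O)C(=C)OP(=O)(O)O
ethanolamine_phosphate	NCCOP(=O)(O)O
adenine	NC1=NC=NC2=C1N=CN2
guanine	NC1=NC2=C(N=CN2)C(=O)N1
cytosine	NC1=NC(=O)NC=C1
uracil	O=C1NC=CC(=O)N1
thymine	CC1=CNC(=O)NC1=O
hypoxanthine	O=C1NC=NC2=C1N=CN2
xanthine	O=C1NC2=C(N=CN2)C(=O)N1
uric_acid	O=C1NC(=O)C2=C(N1)NC(=O)N2
allantoin	NC(=O)NC1NC(=O)NC1=O
orotic_acid	OC(=O)C1=CC(=O)NC(=O)N1
caffeine	CN1C=NC2=C1C(=O)N(C)C(=O)N2C
theobromine	CN1C=NC2=C1C(=O)NC(=O)N2C
adenosine	NC1=NC=NC2=C1N=CN2C1OC(CO)C(O)C1O
uridine	OCC1OC(N2C=CC(=O)NC2=O)C(O)C1O
inosine	OCC1OC(N2C=NC3=C2N=CNC3=O)C(O)C1O
choline	C[N+](C)(C)CCO
betaine	C[N+](C)(C)CC(=O)[O-]
carnitine	C[N+](C)(C)CC(O)CC(=O)[O-]
acetylcholine	CC(=O)OCC[N+](C)(C)C
taurine	NCCS(=O)(=O)O
creatine	CN(CC(=O)O)C(=N)N
creatinine	CN1CC(=O)N=C1N
urea	NC(N)=O
putrescine	NCCCCN
cadaverine	NCCCCCN
spermidine	NCCCCNCCCN
histamine	NCCc1c[nH]cn1
tryptamine	NCCc1c[nH]c2ccccc12
serotonin	NCCc1c[nH]c2ccc(O)cc12
tyramine	NCCc1ccc(O)cc1
dopamine	NCCc1ccc(O)c(O)c1
phenethylamine	NCCc1ccccc1
epinephrine	CNCC(O)c1ccc(O)c(O)c1
gamma_aminobutyric_acid	NCCCC(=O)O
indole_3_acetic_acid	OC(=O)Cc1c[nH]c2ccccc12
kynurenine	NC(CC(=O)c1ccccc1N)C(=O)O
nicotinamide	NC(=O)c1cccnc1
nicotinic_acid	OC(=O)c1cccnc1
pyridoxine	Cc1ncc(CO)c(CO)c1O
pantothenic_acid	OCC(C)(C)C(O)C(=O)NCCC(=O)O
ascorbic_acid	OCC(O)C1OC(=O)C(O)=C1O
biotin	OC(=O)CCCCC1SCC2NC(=O)NC12
glutathione	NC(CCC(=O)NC(CS)C(=O)NCC(=O)O)C(=O)O
caprylic_acid	CCCCCCCC(=O)O
capric_acid	CCCCCCCCCC(=O)O
lauric_acid	CCCCCCCCCCCC(=O)O
myristic_acid	CCCCCCCCCCCCCC(=O)O
palmitic_acid	CCCCCCCCCCCCCCCC(=O)O
stearic_acid	CCCCCCCCCCCCCCCCCC(=O)O
oleic_acid	CCCCCCCCC=CCCCCCCCC(=O)O
linoleic_acid	CCCCCC=CCC=CCCCCCCCC(=O)O
phenol	Oc1ccccc1
catechol	Oc1ccccc1O
p_cresol	Cc1ccc(O)cc1
vanillin	COc1cc(C=O)ccc1O
mevalonic_acid	CC(O)(CCO)CC(=O)O
4_hydroxybenzoic_acid	OC(=O)c1ccc(O)cc1
indole	c1ccc2[nH]ccc2c1
2_deoxyribose	OCC1OC(O)CC1O
threonic_acid	OCC(O)C(O)C(=O)O
4_guanidinobutyric_acid	NC(=N)NCCCC(=O)O
3_methylhistidine	CN1C=NC(=C1)CC(N)C(=O)O
glucosamine	NC1C(O)OC(CO)C(O)C1O
propylene_glycol	CC(O)CO
oxamic_acid	NC(=O)C(=O)O
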