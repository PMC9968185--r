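name,smiles,role
indomethacin,COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1,api
naproxen,COc1ccc2cc(C(C)C(=O)O)ccc2c1,api
ibuprofen,CC(C)Cc1ccc(C(C)C(=O)O)cc1,api
carbamazepine,NC(=O)N1c2ccccc2C=Cc2ccccc21,api
paracetamol,CC(=O)Nc1ccc(O)cc1,api
furosemide,NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl,api
atenolol,CC(C)NCC(O)COc1ccc(CC(N)=O)cc1,api
carvedilol,OC(COc1cccc2[nH]c3ccccc3c12)CNCCOc1ccccc1OC,api
felodipine,CCOC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1cccc(Cl)c1Cl,api
nifedipine,COC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccccc1[N+](=O)[O-],api
mebendazole,COC(=O)Nc1nc2cc(C(=O)c3ccccc3)ccc2[nH]1,api
salbutamol,CC(C)(C)NCC(O)c1ccc(O)c(CO)c1,api
theophylline,Cn1c(=O)c2[nH]cnc2n(C)c1=O,api
isoniazid,NNC(=O)c1ccncc1,api
pyrazinamide,NC(=O)c1cnccn1,api
ethambutol,CCC(CO)NCCNC(CC)CO,api
glycine,NCC(=O)O,amino_acid
alanine,CC(N)C(=O)O,amino_acid
valine,CC(C)C(N)C(=O)O,amino_acid
leucine,CC(C)CC(N)C(=O)O,amino_acid
proline,OC(=O)C1CCCN1,amino_acid
serine,OCC(N)C(=O)O,amino_acid
threonine,CC(O)C(N)C(=O)O,amino_acid
phenylalanine,NC(Cc1ccccc1)C(=O)O,amino_acid
tryptophan,NC(Cc1c[nH]c2ccccc12)C(=O)O,amino_acid
arginine,NC(CCCNC(=N)N)C(=O)O,amino_acid
lysine,NCCCCC(N)C(=O)O,amino_acid
histidine,NC(Cc1c[nH]cn1)C(=O)O,amino_acid
citric acid,OC(=O)CC(O)(CC(=O)O)C(=O)O,organic_acid
tartaric acid,OC(C(O)C(=O)O)C(=O)O,organic_acid
succinic acid,OC(=O)CCC(=O)O,organic_acid
malic acid,OC(CC(=O)O)C(=O)O,organic_acid
fumaric acid,OC(=O)C=CC(=O)O,organic_acid
benzoic acid,OC(=O)c1ccccc1,organic_acid
salicylic acid,OC(=O)c1ccccc1O,organic_acid
oxalic acid,OC(=O)C(=O)O,organic_acid
glutaric acid,OC(=O)CCCC(=O)O,organic_acid
adipic acid,OC(=O)CCCCC(=O)O,organic_acid
nicotinamide,NC(=O)c1cccnc1,other
urea,NC(N)=O,other
saccharin,O=C1NS(=O)(=O)c2ccccc12,other
sorbitol,OCC(O)C(O)C(O)C(O)CO,other
glucose,OCC1OC(O)C(O)C(O)C1O,other
xylitol,OCC(O)C(O)C(O)CO,other
glycerol,OCC(O)CO,other
taurine,NCCS(=O)(=O)O,other
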