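name,smiles
salbutamol,CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
formoterol,CC(Cc1ccc(OC)cc1)NCC(O)c1ccc(O)c(NC=O)c1
bambuterol,CC(C)(C)NCC(O)c1cc(OC(=O)N(C)C)cc(OC(=O)N(C)C)c1
theophylline,Cn1c(=O)c2[nH]cnc2n(C)c1=O
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C
isoniazid,NNC(=O)c1ccncc1
pyrazinamide,NC(=O)c1cnccn1
ethambutol,CCC(CO)NCCNC(CC)CO
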