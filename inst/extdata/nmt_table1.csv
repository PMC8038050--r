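id,smiles,ic50_um,pic50
20,Cn(n1)c(C)c(c1C)N(C(F)F)S(=O)(=O)c(c(Cl)c2)c(Cl)cc2CCCO[C@H](C3)C[C@@H](N4C)CC[C@H]34,0.002,8.699
73,Cn(n1)c(C)c(c1C)NS(=O)(=O)c(c(Cl)c2)c(Cl)cc2-c3cc(ncc3)N4CCNCC4,0.003,8.523
2,Cn(n1)c(C)c(c1C)NS(=O)(=O)c(cc2)c(Cl)cc2-c3cc(ncc3)N4CCNCC4,0.004,8.398
78,CC(C)Cc1c(c(C)n(n1)C)NS(=O)(=O)c(c(Cl)c2)c(Cl)cc2-c3cc(ncc3)N4CCNCC4,0.004,8.398
95,C1CN(C)CCC1CCCCc2cc(Cl)c(c(Cl)c2)S(=O)(=O)Nc(c3C)c(C)n(n3)C,0.004,8.398
293,CC(C)Cc1ccc2ncccc2c1NS(=O)(=O)c1ccc(CCCO[C@H]2C[C@@H]3CC[C@H](C2)N3C)cc1,27000,1.569
82,Cc1c(C)c(OC)cc(C)c1S(=O)(=O)Nc(c2C)cccn2,70000,1.155
83,Cn1ncc(c1C)NS(=O)(=O)c2c(Cl)cc(Br)cc2Cl,70800,1.15
84,Cn(n1)c(C)c(c1C)NS(=O)(=O)c(c2F)ccc(Br)c2,87000,1.06
111,Cn(n1)c(C)c(c1C)NS(=O)(=O)c(c2C)ccc(Br)c2,107000,0.971
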