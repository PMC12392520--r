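id,smiles,response
MOL001,CCO,4.21
MOL002,CC(=O)Oc1ccccc1C(=O)O,5.10
MOL003,c1ccccc1,4.02
MOL004,CC(C)Cc1ccc(cc1)C(C)C(=O)O,5.87
MOL005,CN1C=NC2=C1C(=O)N(C(=O)N2C)C,6.02
MOL006,C1CCCCC1,4.15
MOL007,CC(=O)Nc1ccc(O)cc1,5.45
MOL008,Clc1ccccc1,4.60
MOL009,OCC(O)CO,4.35
MOL010,CC(C)NCC(O)COc1ccc2ccccc2c1,6.80
MOL011,Nc1ccc(cc1)S(=O)(=O)N,5.22
MOL012,COc1cc2c(cc1OC)CC(N)C2,6.31
MOL013,O=C(O)c1ccccc1O,4.88
MOL014,CCN(CC)CCNC(=O)c1ccc(N)cc1,6.55
MOL015,CC12CCC3c4ccc(O)cc4CCC3C1CCC2O,7.10
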