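name,smiles,role
"Isosorbide","OC1COC2C(O)COC12","diol"
"Sorbitol","OCC(O)C(O)C(O)C(O)CO","polyol"
"Xylitol","OCC(O)C(O)C(O)CO","polyol"
"Curcumin","COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O","diol"
"PEG400","OCCOCCOCCOCCOCCOCCOCCOCCOCCO","diol"
"1,3-Propanediol","OCCCO","diol"
"1,2-Propanediol","CC(O)CO","diol"
"1,4-Cyclohexanedimethanol","OCC1CCC(CO)CC1","diol"
"3-Methyl-1,5-pentanediol","OCCC(C)CCO","diol"
"1,10-Decanediol","OCCCCCCCCCCO","diol"
"1,6-Hexanediol","OCCCCCCO","diol"
"2-Butene-1,4-diol","OCC=CCO","diol"
"2,2-Dimethyl-1,3-propanediol","OCC(C)(C)CO","diol"
"Diethylene glycol","OCCOCCO","diol"
"Glycerol","OCC(O)CO","polyol"
"Diglycerol","OCC(O)COCC(O)CO","polyol"
"1,4-Butanediol","OCCCCO","diol"
"Triethylene glycol","OCCOCCOCCO","diol"
"Tetraethylene glycol","OCCOCCOCCOCCO","diol"
"Ethylene glycol","OCCO","diol"
"Dimethyl furan-2,5-dicarboxylate","COC(=O)c1ccc(o1)C(=O)OC","dimethyl_ester"
"Dimethyl succinate","COC(=O)CCC(=O)OC","dimethyl_ester"
"Dimethyl suberate","COC(=O)CCCCCCC(=O)OC","dimethyl_ester"
"Dimethyl azelate","COC(=O)CCCCCCCC(=O)OC","dimethyl_ester"
"Dimethyl adipate","COC(=O)CCCCC(=O)OC","dimethyl_ester"
"Dimethyl sebacate","COC(=O)CCCCCCCCC(=O)OC","dimethyl_ester"
"Dimethyl fumarate","COC(=O)C=CC(=O)OC","dimethyl_ester"
"Dimethyl isophthalate","COC(=O)c1cccc(C(=O)OC)c1","dimethyl_ester"
"Dimethyl terephthalate","COC(=O)c1ccc(C(=O)OC)cc1","dimethyl_ester"
"Dimethyl glutarate","COC(=O)CCCC(=O)OC","dimethyl_ester"
"Cyclobutane-1,1-dicarboxylic acid","OC(=O)C1(C(=O)O)CCC1","diacid"
"Succinic acid","OC(=O)CCC(=O)O","diacid"
"Glutaric acid","OC(=O)CCCC(=O)O","diacid"
"Adipic acid","OC(=O)CCCCC(=O)O","diacid"
"Suberic acid","OC(=O)CCCCCCC(=O)O","diacid"
"Azelaic acid","OC(=O)CCCCCCCC(=O)O","diacid"
"Sebacic acid","OC(=O)CCCCCCCCC(=O)O","diacid"
"Terephthalic acid","OC(=O)c1ccc(C(=O)O)cc1","diacid"
"Isophthalic acid","OC(=O)c1cccc(C(=O)O)c1","diacid"
"Furan-2,5-dicarboxylic acid","OC(=O)c1ccc(o1)C(=O)O","diacid"
"epsilon-Caprolactone","O=C1CCCCCO1","lactone"
"delta-Valerolactone","O=C1CCCCO1","lactone"
"Lactide","CC1OC(=O)C(C)OC1=O","lactone"
"Glycolide","O=C1COC(=O)CO1","lactone"
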