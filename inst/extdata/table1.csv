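id,monomer1,monomer2,mn,mw,dispersity,biodegradable,in_literature
1,"Isosorbide","Dimethyl furan-2,5-dicarboxylate",610,870,1.4,Yes,0
2,"Sorbitol","Dimethyl succinate",n.d.,n.d.,n.d.,No,0
3,"Sorbitol","Dimethyl suberate",510,4745,9.3,No,0
4,"Sorbitol","Dimethyl azelate",680,3472,5.1,No,0
5,"Xylitol","Dimethyl adipate",4160,7410,1.8,No,0
6,"Curcumin","Dimethyl fumarate",1030,1270,1.2,No,0
7,"Isosorbide","Dimethyl fumarate",1780,2895,1.6,Yes,0
8,"Glycerol","Dimethyl suberate",1725,2225,1.3,Yes,0
9,"1,3-Propanediol","Cyclobutane-1,1-dicarboxylic acid",470,580,1.2,Yes,0
10,"PEG400","Dimethyl adipate",2065,3305,1.6,No,0
11,"PEG400","Dimethyl furan-2,5-dicarboxylate",3045,4450,1.5,No,0
12,"1,2-Propanediol","Dimethyl isophthalate",2080,3545,1.7,No,1
13,"1,4-Cyclohexanedimethanol","Dimethyl terephthalate",n.d.,n.d.,n.d.,No,1
14,"3-Methyl-1,5-pentanediol","Dimethyl terephthalate",2795,4480,1.6,No,1
15,"1,10-Decanediol","Dimethyl terephthalate",n.d.,n.d.,n.d.,No,1
16,"1,6-Hexanediol","Dimethyl furan-2,5-dicarboxylate",n.d.,n.d.,n.d.,No,1
17,"2-Butene-1,4-diol","Dimethyl succinate",1345,3530,2.5,Yes,1
18,"3-Methyl-1,5-pentanediol","Dimethyl succinate",3120,6385,2.0,Yes,1
19,"1,10-Decanediol","Dimethyl succinate",915,2900,3.2,No,1
20,"2,2-Dimethyl-1,3-propanediol","Dimethyl adipate",1030,1620,1.6,No,1
21,"1,6-Hexanediol","Dimethyl adipate",6135,11430,1.9,No,1
22,"Diethylene glycol","Dimethyl adipate",5835,10860,1.8,Yes,1
23,"1,4-Cyclohexanedimethanol","Dimethyl sebacate",910,1880,2.1,No,1
24,"1,10-Decanediol","Dimethyl sebacate",871,1070,1.2,No,1
25,"1,6-Hexanediol","Dimethyl sebacate",7470,13680,1.8,No,1
26,"Diethylene glycol","Dimethyl sebacate",2510,6260,2.5,Yes,1
27,"Glycerol","Dimethyl furan-2,5-dicarboxylate",1480,2115,1.4,Yes,0
28,"Glycerol","Dimethyl succinate",3130,5795,1.9,Yes,0
29,"Glycerol","Dimethyl adipate",2465,3485,1.4,Yes,0
30,"Glycerol","Dimethyl azelate",2490,3820,1.5,Yes,0
31,"Glycerol","Dimethyl sebacate",2410,3291,1.4,Yes,0
32,"Diglycerol","Dimethyl succinate",3310,4595,1.4,Yes,0
33,"Diglycerol","Dimethyl adipate",3945,7045,1.8,No,0
34,"Diglycerol","Dimethyl azelate",4405,9690,2.2,Yes,0
35,"Diglycerol","Dimethyl furan-2,5-dicarboxylate",2210,3290,1.5,Yes,0
36,"Diglycerol","Dimethyl azelate",1350,1665,1.2,Yes,0
37,"Diglycerol","Dimethyl sebacate",3950,6330,1.6,Yes,0
38,"Diglycerol","Dimethyl suberate",3295,4355,1.3,Yes,0
39,"1,3-Propanediol","Dimethyl furan-2,5-dicarboxylate",n.d.,n.d.,n.d.,Yes,0
40,"1,3-Propanediol","Dimethyl succinate",1450,2785,1.9,Yes,1
41,"PEG400","Dimethyl succinate",1950,3085,1.6,No,0
42,"PEG400","Dimethyl suberate",1500,2105,1.4,Yes,0
43,"PEG400","Dimethyl azelate",1340,1785,1.3,Yes,0
44,"PEG400","Dimethyl sebacate",1970,3100,1.6,Yes,0
45,"epsilon-Caprolactone","",9120,12900,1.4,No,1
46,"delta-Valerolactone","",6940,13360,1.4,No,1
47,"Lactide","",12830,15300,1.2,No,1
48,"Lactide","Glycolide",4990,14690,2.9,Yes,1
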