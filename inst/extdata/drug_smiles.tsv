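name	smiles
curcumin	COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O
triamcinolone acetonide	CC1(C)O[C@@H]2C[C@H]3[C@@H]4CCC5=CC(=O)C=C[C@]5(C)[C@@]4(F)[C@@H](O)C[C@]3(C)[C@@]2(O1)C(=O)CO
paclitaxel	CC(=O)O[C@@H]1C(=O)[C@]2(C)[C@@H](O)C[C@H]3OC[C@@]3(OC(C)=O)[C@H]2[C@H](OC(=O)c2ccccc2)[C@]2(O)C[C@H](OC(=O)[C@H](O)[C@@H](NC(=O)c3ccccc3)c3ccccc3)C(C)=C1C2(C)C
celecoxib	Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1
efavirenz	C1CC1C#C[C@]1(C(F)(F)F)OC(=O)Nc2ccc(Cl)cc21
indomethacin	COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1
cannabidiol	CCCCCc1cc(O)c([C@@H]2C=C(C)CC[C@H]2C(C)=C)c(O)c1
ibuprofen	CC(C)Cc1ccc(C(C)C(=O)O)cc1
naproxen	COc1ccc2cc([C@@H](C)C(=O)O)ccc2c1
ketoprofen	CC(C(=O)O)c1cccc(C(=O)c2ccccc2)c1
diclofenac	O=C(O)Cc1ccccc1Nc1c(Cl)cccc1Cl
griseofulvin	COC1=CC(=O)C[C@@H](C)[C@@]12Oc1c(Cl)c(OC)cc(OC)c1C2=O
carbamazepine	NC(=O)N1c2ccccc2C=Cc2ccccc21
phenytoin	O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1
diazepam	CN1c2ccc(Cl)cc2C(c2ccccc2)=NCC1=O
nifedipine	COC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccccc1[N+](=O)[O-]
felodipine	CCOC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1cccc(Cl)c1Cl
fenofibrate	CC(C)OC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1
tamoxifen	CC/C(=C(\c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1
estradiol	C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc43)[C@@H]1CC[C@@H]2O
testosterone	C[C@]12CC[C@H]3[C@@H](CCC4=CC(=O)CC[C@]34C)[C@@H]1CC[C@@H]2O
progesterone	CC(=O)[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C
dexamethasone	C[C@@H]1C[C@H]2[C@@H]3CCC4=CC(=O)C=C[C@]4(C)[C@@]3(F)[C@@H](O)C[C@]2(C)[C@@]1(O)C(=O)CO
hydrocortisone	OCC(=O)[C@@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]21C
quercetin	O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
resveratrol	Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1
genistein	O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12
clotrimazole	Clc1ccccc1C(c1ccccc1)(c1ccccc1)n1ccnc1
haloperidol	O=C(CCCN1CCC(O)(c2ccc(Cl)cc2)CC1)c1ccc(F)cc1
mitotane	ClC(Cl)C(c1ccccc1Cl)c1ccc(Cl)cc1
simvastatin	CCC(C)(C)C(=O)O[C@H]1C[C@@H](C)C=C2C=C[C@H](C)[C@H](CC[C@@H]3C[C@@H](O)CC(=O)O3)[C@H]12
probucol	CC(C)(C)c1cc(SC(C)(C)Sc2cc(C(C)(C)C)c(O)c(C(C)(C)C)c2)cc(C(C)(C)C)c1O
olanzapine	Cc1cc2c(s1)Nc1ccccc1N=C2N1CCN(C)CC1
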