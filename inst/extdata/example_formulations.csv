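a_monomer,b_monomer,nA1,nB,nA2,terminus_start,terminus_end,polymer_feed,drug1,drug1_smiles,drug1_feed,drug1_solubilized,t_days
MeOx,nPrOzi,35,20,35,Me,Pip,10,curcumin,COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O,8,7.5,0
MeOx,nBuOx,35,20,35,Me,Pip,10,curcumin,COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O,8,3.2,0
MeOx,nBuOx,35,20,35,Me,Pip,10,paclitaxel,CC(=O)O[C@@H]1C(=O)[C@]2(C)[C@@H](O)C[C@H]3OC[C@@]3(OC(C)=O)[C@H]2[C@H](OC(=O)c2ccccc2)[C@]2(O)C[C@H](OC(=O)[C@H](O)[C@@H](NC(=O)c3ccccc3)c3ccccc3)C(C)=C1C2(C)C,4,3.1,0
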