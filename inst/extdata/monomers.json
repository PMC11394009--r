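{
  "comment": "Registry of 2-oxazoline (Ox) / 2-oxazine (Ozi) repeat units and chain termini. Attachment points are written as [*]; for repeat units the first [*] is the backbone nitrogen side, the last [*] the backbone carbon tail. 'capped' entries override the automatic capping rule when present.",
  "monomers": {
    "MeOx":    { "role": "A", "smiles": "[*]N(C(C)=O)CC[*]" },
    "EtOx":    { "role": "A", "smiles": "[*]N(C(=O)CC)CC[*]" },
    "nPrOx":   { "role": "B", "smiles": "[*]N(C(=O)CCC)CC[*]" },
    "nBuOx":   { "role": "B", "smiles": "[*]N(C(=O)CCCC)CC[*]" },
    "PentOx":  { "role": "B", "smiles": "[*]N(C(=O)CCCCC)CC[*]" },
    "PhOx":    { "role": "B", "smiles": "[*]N(C(=O)c1ccccc1)CC[*]" },
    "BzOx":    { "role": "B", "smiles": "[*]N(C(=O)Cc1ccccc1)CC[*]" },
    "PhenOx":  { "role": "B", "smiles": "[*]N(C(=O)CCc1ccccc1)CC[*]" },
    "nPrOzi":  { "role": "B", "smiles": "[*]N(C(=O)CCC)CCC[*]" },
    "nBuOzi":  { "role": "B", "smiles": "[*]N(C(=O)CCCC)CCC[*]" },
    "PhOzi":   { "role": "B", "smiles": "[*]N(C(=O)c1ccccc1)CCC[*]" },
    "BzOzi":   { "role": "B", "smiles": "[*]N(C(=O)Cc1ccccc1)CCC[*]" },
    "PhenOzi": { "role": "B", "smiles": "[*]N(C(=O)CCc1ccccc1)CCC[*]" }
  },
  "termini": {
    "Me":  { "role": "terminus_start", "smiles": "[*]C" },
    "OH":  { "role": "terminus_end",   "smiles": "[*]O" },
    "Pip": { "role": "terminus_end",   "smiles": "[*]N1CCCCC1" },
    "EDA": { "role": "terminus_end",   "smiles": "[*]NCCN" }
  }
}
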