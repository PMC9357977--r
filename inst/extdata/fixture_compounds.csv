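id,smiles,label
naringin,CC1C(C(C(C(O1)OC2C(C(C(OC2OC3=CC(=C4C(=C3)OC(CC4=O)C5=CC=C(C=C5)O)O)CO)O)O)O)O)O,active
quercetin,C1=CC(=C(C=C1C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O)O)O,active
kaempferol,C1=CC(=CC=C1C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O)O,active
beta_sitosterol,CCC(CCC(C)C1CCC2C1(CCC3C2CC=C4C3(CCC(C4)O)C)C)C(C)C,active
isorhamnetin,COC1=C(C=CC(=C1)C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O)O,active
stigmasterol,CCC(C=CC(C)C1CCC2C1(CCC3C2CC=C4C3(CCC(C4)O)C)C)C(C)C,active
icariin,CC1C(C(C(C(O1)OC2=C(OC3=CC(=CC(=C3C2=O)O)OC4C(C(C(C(O4)CO)O)O)O)C5=CC=C(C=C5)OC)O)O)O,active
aspirin,CC(=O)OC1=CC=CC=C1C(=O)O,inactive
caffeine,CN1C=NC2=C1C(=O)N(C(=O)N2C)C,inactive
ibuprofen,CC(C)CC1=CC=C(C=C1)C(C)C(=O)O,inactive
glucose,C(C1C(C(C(C(O1)O)O)O)O)O,inactive
benzene,c1ccccc1,inactive
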