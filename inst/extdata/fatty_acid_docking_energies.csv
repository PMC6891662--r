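ligand,conformer,binding_energy_kcal_mol
Arachidonic acid,1,-8.06
Caffeic acid,1,-6.40
Ferulic acid,1,-6.47
Linoleic acid,1,-6.37
Linolenic acid,1,-8.35
Palmitic acid,1,-8.69
p-Coumarate,1,-6.41
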