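# read-frequency trend predictions vs qPCR-observed patterns for the
# 17 blueberry cold-acclimation and fruit-ripening genes tested
gene	group	predicted	observed
pyrophosphate_dependent_phosphofructokinase	bud	down_up	down_up
arginine_decarboxylase	bud	down_up	down_up
lipoxygenase	bud	down	down
abscisic_stress_ripening	bud	down_up	down_up
hypothetical_protein	bud	down_up	down_up
lipid_transfer_protein	bud	up_down	down_up
amino_acid_selective_channel	bud	up_down	up_down
pointed_first_leaf	bud	up	up
high_mobility_group	bud	up_down	up_down
pectate_lyase	fruit	up_down	up_down
cysteine_protease	fruit	up_down	complex
glutathione_peroxidase	fruit	up_down	up_down
chalcone_synthase	fruit	up_down	up_down
anthocyanidin_synthase	fruit	up_down	up_down
aspartic_proteinase	fruit	up	flat
acc_oxidase	fruit	up	up
flavonoid_3_hydroxylase	fruit	up	up
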