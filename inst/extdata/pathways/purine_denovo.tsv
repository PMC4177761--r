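step_id	substrates	products	ec_list	reversible	tags	diagram
r1p_r5p	R1P	R5P	5.4.2.2,5.4.2.7	TRUE	de_novo	purine_de_novo
r5p_prpp	R5P	PRPP	2.7.6.1	FALSE	de_novo	purine_de_novo
prpp_pra	PRPP	PRA	2.4.2.14	FALSE	de_novo	purine_de_novo
pra_gar	PRA	GAR	6.3.4.13	FALSE	de_novo	purine_de_novo
gar_fgar	GAR	FGAR	2.1.2.2	FALSE	de_novo	purine_de_novo
fgar_fgam	FGAR	FGAM	6.3.5.3	FALSE	de_novo	purine_de_novo
fgam_air	FGAM	AIR	6.3.3.1	FALSE	de_novo	purine_de_novo
air_cair	AIR	CAIR	4.1.1.21	FALSE	de_novo,one_step_carboxylation	purine_de_novo
air_ncair	AIR	NCAIR	6.3.4.18	FALSE	de_novo,bicarbonate_dependent	purine_de_novo
ncair_cair	NCAIR	CAIR	5.4.99.18	FALSE	de_novo	purine_de_novo
cair_saicar	CAIR	SAICAR	6.3.2.6	FALSE	de_novo	purine_de_novo
saicar_aicar	SAICAR	AICAR	4.3.2.2	FALSE	de_novo	purine_de_novo
aicar_faicar	AICAR	FAICAR	2.1.2.3,6.3.4.23	FALSE	de_novo,folate_dependent,archaea_specific	purine_de_novo
faicar_imp	FAICAR	IMP	3.5.4.10	FALSE	de_novo,folate_dependent,archaea_specific	purine_de_novo
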