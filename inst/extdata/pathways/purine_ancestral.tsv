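step_id	substrates	products	ec_list	reversible	tags	diagram
r1p_r5p	R1P	R5P	5.4.2.2	TRUE		purine_ancestral
r5p_prpp	R5P	PRPP	2.7.6.1	FALSE		purine_ancestral
hx_imp	hypoxanthine,PRPP	IMP	2.4.2.8	FALSE	salvage	purine_ancestral
aica_aicar	AICA,PRPP	AICAR	2.4.2.7,2.4.2.8	FALSE	salvage,broad_specificity	purine_ancestral
aicar_imp	AICAR	IMP		FALSE	nonenzymatic,semienzymatic	purine_ancestral
aicar_thi	AICAR	thiamine_phosphate		FALSE	nonenzymatic,thiamine_branch	purine_ancestral
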