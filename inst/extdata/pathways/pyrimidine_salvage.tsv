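step_id	substrates	products	ec_list	reversible	tags	diagram
ura_urd	uracil,R1P	uridine	2.4.2.3	TRUE	salvage	pyrimidine_salvage
urd_ump	uridine	UMP	2.7.1.48	FALSE	salvage	pyrimidine_salvage
ura_ump	uracil,PRPP	UMP	2.4.2.9	FALSE	salvage	pyrimidine_salvage
cyt_cyd	cytosine,R1P	cytidine	2.4.2.2	TRUE	salvage	pyrimidine_salvage
cyd_urd	cytidine	uridine	3.5.4.5	FALSE	salvage	pyrimidine_salvage
cyd_cmp	cytidine	CMP	2.7.1.48	FALSE	salvage	pyrimidine_salvage
dcyd_dcmp	deoxycytidine	dCMP	2.7.1.74	FALSE	salvage	pyrimidine_salvage
thy_tdr	thymine,dR1P	thymidine	2.4.2.4	TRUE	salvage	pyrimidine_salvage
tdr_dtmp	thymidine	dTMP	2.7.1.21	FALSE	salvage	pyrimidine_salvage
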