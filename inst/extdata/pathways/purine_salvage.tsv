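step_id	substrates	products	ec_list	reversible	tags	diagram
hx_imp	hypoxanthine,PRPP	IMP	2.4.2.8	FALSE	salvage	purine_salvage
ade_amp	adenine,PRPP	AMP	2.4.2.7	FALSE	salvage	purine_salvage
gua_gmp	guanine,PRPP	GMP	2.4.2.8	FALSE	salvage	purine_salvage
imp_amps	IMP	AMPS	6.3.4.4	FALSE	de_novo	purine_salvage
amps_amp	AMPS	AMP	4.3.2.2	FALSE	de_novo	purine_salvage
amp_adp	AMP	ADP	2.7.4.3	FALSE		purine_salvage
adp_atp	ADP	ATP	2.7.4.6,2.7.1.40	FALSE		purine_salvage
adp_dadp	ADP	dADP	1.17.4.1	FALSE		purine_salvage
atp_datp	ATP	dATP	1.17.4.2	FALSE	anaerobic_alternative	purine_salvage
dadp_datp	dADP	dATP	2.7.4.6,2.7.1.40	FALSE		purine_salvage
imp_xmp	IMP	XMP	1.1.1.205	FALSE		purine_salvage
xmp_gmp	XMP	GMP	6.3.5.2,6.3.4.1	FALSE		purine_salvage
gmp_gdp	GMP	GDP	2.7.4.8	FALSE		purine_salvage
gdp_gtp	GDP	GTP	2.7.4.6,2.7.1.40	FALSE		purine_salvage
gdp_dgdp	GDP	dGDP	1.17.4.1	FALSE		purine_salvage
dgdp_dgtp	dGDP	dGTP	2.7.4.6,2.7.1.40	FALSE		purine_salvage
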