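step_id	substrates	products	ec_list	reversible	tags	diagram
ump_udp	UMP	UDP	2.7.4.14,2.7.4.22	FALSE		pyrimidine_from_ump
udp_utp	UDP	UTP	2.7.4.6	FALSE		pyrimidine_from_ump
utp_ctp	UTP	CTP	6.3.4.2	FALSE		pyrimidine_from_ump
cdp_ctp	CDP	CTP	2.7.4.6	TRUE		pyrimidine_from_ump
cdp_dcdp	CDP	dCDP	1.17.4.1	FALSE	thioredoxin_coupled	pyrimidine_from_ump
dcdp_dctp	dCDP	dCTP	2.7.4.6	FALSE		pyrimidine_from_ump
udp_dudp	UDP	dUDP	1.17.4.1	FALSE	thioredoxin_coupled	pyrimidine_from_ump
dudp_dutp	dUDP	dUTP	2.7.4.6	FALSE		pyrimidine_from_ump
dutp_dump	dUTP	dUMP	3.6.1.19,3.6.1.23	FALSE		pyrimidine_from_ump
dctp_dutp	dCTP	dUTP	3.5.4.13	FALSE		pyrimidine_from_ump
dcmp_dump	dCMP	dUMP	3.5.4.12	FALSE		pyrimidine_from_ump
dump_dtmp	dUMP	dTMP	2.1.1.45,2.1.1.148	FALSE	folate_dependent	pyrimidine_from_ump
dtmp_dtdp	dTMP	dTDP	2.7.4.9	FALSE		pyrimidine_from_ump
dtdp_dttp	dTDP	dTTP	2.7.4.6	FALSE		pyrimidine_from_ump
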