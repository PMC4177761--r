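step_id	substrates	products	ec_list	reversible	tags	diagram
gln_cap	glutamine,HCO3	carbamoyl_phosphate	6.3.5.5	FALSE	de_novo	pyrimidine_de_novo
cap_ca	carbamoyl_phosphate,aspartate	carbamoyl_aspartate	2.1.3.2	FALSE	de_novo	pyrimidine_de_novo
ca_dho	carbamoyl_aspartate	dihydroorotate	3.5.2.3	FALSE	de_novo	pyrimidine_de_novo
dho_oro	dihydroorotate	orotate	1.3.1.14,1.3.5.2,1.3.98.1	FALSE	de_novo	pyrimidine_de_novo
oro_omp	orotate,PRPP	OMP	2.4.2.10	FALSE	de_novo	pyrimidine_de_novo
omp_ump	OMP	UMP	4.1.1.23	FALSE	de_novo	pyrimidine_de_novo
ump_udp	UMP	UDP	2.7.4.14,2.7.4.22	FALSE	de_novo	pyrimidine_de_novo
udp_utp	UDP	UTP	2.7.4.6	FALSE	de_novo	pyrimidine_de_novo
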