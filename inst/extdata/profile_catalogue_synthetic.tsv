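profile_id	ec_number	role	group_id	superfamily	profile_length
PGM	5.4.2.2	single			710
DeoB	5.4.2.7	single			470
PrsA	2.7.6.1	single		PRTase-like	302
PurF	2.4.2.14	single		PRTase-like	223
PurD	6.3.4.13	single		ATP-grasp	377
PurN	2.1.2.2	analog	gar_tfase	Formyltransferase	295
PurT	2.1.2.2	analog	gar_tfase	ATP-grasp	783
PurQ	6.3.5.3	subunit	fgam_synthase		198
PurL	6.3.5.3	subunit	fgam_synthase		277
PurM	6.3.3.1	single			452
PurK	6.3.4.18	single		ATP-grasp	173
PurE	5.4.99.18	single		N5-CAIR-mutase	988
AIRC	4.1.1.21	single		N5-CAIR-mutase	505
PurC	6.3.2.6	single			750
PurB	4.3.2.2	single			314
PurH_ATFC	2.1.2.3	single			771
PurH_IMPCH	3.5.4.10	analog	imp_cyclohydrolase		681
PurO	3.5.4.10	analog	imp_cyclohydrolase		559
PurP	6.3.4.23	single		ATP-grasp	1031
Hpt1	2.4.2.8	paralog	hgprt	PRTase	1028
Hpt2	2.4.2.8	paralog	hgprt	PRTase	1048
Apt	2.4.2.7	single		PRTase	446
Adk	2.7.4.3	paralog	adenylate_kinase	P-loop-NTPase	750
Adk6	2.7.4.3	paralog	adenylate_kinase	P-loop-NTPase	432
Ndk	2.7.4.6	paralog	ndk		1081
Ndk2	2.7.4.6	paralog	ndk		770
PykF	2.7.1.40	single			666
NrdA	1.17.4.1	subunit	rnr_class1		361
NrdB	1.17.4.1	subunit	rnr_class1		1079
NrdE	1.17.4.1	subunit	rnr_class1b		1009
NrdF	1.17.4.1	subunit	rnr_class1b		1021
NrdJ	1.17.4.2	single			408
NrdD	1.17.4.2	subunit	rnr_anaerobic		463
NrdG	1.17.4.2	subunit	rnr_anaerobic		630
GuaB1	1.1.1.205	paralog	impdh		447
GuaB2	1.1.1.205	paralog	impdh		173
GuaAA	6.3.5.2	subunit	gmp_synthase		307
GuaAB	6.3.5.2	subunit	gmp_synthase		448
GuaA_NH3	6.3.4.1	single			1060
Gmk1	2.7.4.8	paralog	guanylate_kinase	P-loop-NTPase	555
Gmk2	2.7.4.8	paralog	guanylate_kinase	P-loop-NTPase	463
PurA	6.3.4.4	single			797
CarA	6.3.5.5	subunit	cps		441
CarB	6.3.5.5	subunit	cps		985
PyrB1	2.1.3.2	paralog	atcase		295
PyrB2	2.1.3.2	paralog	atcase		770
PyrC1	3.5.2.3	paralog	dhoase		497
PyrC2	3.5.2.3	paralog	dhoase		346
PyrDb_cat	1.3.1.14	subunit	dhod_b	FMN-oxidoreductase	665
PyrDb_et	1.3.1.14	subunit	dhod_b	FMN-oxidoreductase	375
PyrD2	1.3.5.2	single		FMN-oxidoreductase	653
PyrDa	1.3.98.1	single		FMN-oxidoreductase	1095
PyrE1	2.4.2.10	paralog	oprt	PRTase	504
PyrE2	2.4.2.10	paralog	oprt	PRTase	876
PyrF1	4.1.1.23	paralog	ompdc		1094
PyrF2	4.1.1.23	paralog	ompdc		394
Cmk	2.7.4.14	single		P-loop-NTPase	1071
PyrG1	6.3.4.2	paralog	ctp_synthase		775
PyrG2	6.3.4.2	paralog	ctp_synthase		411
TrxB	1.8.1.9	single			539
Ntpp1	3.6.1.19	paralog	ntp_ppase		279
Ntpp2	3.6.1.19	paralog	ntp_ppase		521
ComEB	3.5.4.12	single			152
Dcd	3.5.4.13	single			523
ThyA	2.1.1.45	single			554
ThyX	2.1.1.148	single			919
Udk	2.7.1.48	single		P-loop-NTPase	1019
Udp	2.4.2.3	single			847
Cdd1	3.5.4.5	paralog	cytidine_deaminase		799
Cdd2	3.5.4.5	paralog	cytidine_deaminase		189
Pdp	2.4.2.2	single			666
Upp	2.4.2.9	single		PRTase	182
Dck	2.7.1.74	single			1094
Tdk1	2.7.1.21	paralog	thymidine_kinase	P-loop-NTPase	252
Tdk2	2.7.1.21	paralog	thymidine_kinase	P-loop-NTPase	377
DeoA	2.4.2.4	single			258
GuaC	1.7.1.7	single			478
XdhA	1.17.1.4	subunit	xanthine_dh		818
XdhB	1.17.1.4	subunit	xanthine_dh		225
Xo	1.17.3.2	single			926
PucL	1.7.3.3	single			640
UraH	3.5.2.17	single			696
UraD	4.1.1.97	single			882
PucH	3.5.2.5	single			165
Alc	3.5.3.4	single			506
AllC	3.5.3.9	single			881
AllA	3.5.3.19	single			397
Glx	1.1.1.154	single			474
Ugl	4.3.2.3	single			779
UreC	3.5.1.5	single			791
DeoD1	2.4.2.1	paralog	pnp		231
DeoD2	2.4.2.1	paralog	pnp		1069
PunB	2.4.2.15	single			1030
Gpt	2.4.2.22	single		PRTase	1063
Ntd	2.4.2.6	single			474
Nrt	2.4.2.5	single			771
Mtap	2.4.2.28	single			509
Mtn	3.2.2.16	single			1100
AdoK1	2.7.1.20	paralog	adenosine_kinase		445
AdoK2	2.7.1.20	paralog	adenosine_kinase		298
Gsk	2.7.1.73	single			718
Dgk	2.7.1.113	single			249
Dak	2.7.1.76	single			447
RbsK	2.7.1.15	single			551
PsuK	2.7.1.83	single			240
NuPT	2.7.1.77	single			930
UshA	3.1.3.5	paralog	nucleotidase_5p		330
SurE	3.1.3.5	paralog	nucleotidase_5p		203
Nt3	3.1.3.6	single			1000
TmpP	3.1.3.35	single			437
CpdB	3.1.4.16	single			869
Nuh	3.2.2.1	single			907
Iunh	3.2.2.2	single			209
Amn	3.2.2.4	single			434
Anh	3.2.2.7	single			998
Rih	3.2.2.8	single			769
Urh	3.2.2.3	single			526
PyNP5	3.2.2.10	single			1002
Ade	3.5.4.2	single			787
GuaD	3.5.4.3	single			576
Add1	3.5.4.4	paralog	adenosine_deaminase		591
Add2	3.5.4.4	paralog	adenosine_deaminase		261
AmpD	3.5.4.6	single			733
CodA	3.5.4.1	paralog	cytosine_deaminase		434
CodA2	3.5.4.1	paralog	cytosine_deaminase		1100
Apy	3.6.1.5	single			1083
AtpD	3.6.1.8	single			662
NudF	3.6.1.13	single			290
ApaH	3.6.1.17	single			867
Ntp6	3.6.1.6	single			1050
Ntp3	3.6.1.3	single			460
Dut	3.6.1.23	single			1061
Npp	3.6.1.9	single			623
Itpa	3.6.1.66	single			960
MazG	3.6.1.12	single			703
Apa1	2.7.7.53	single			191
SpoT	3.6.1.40	single			909
RelA	2.7.6.5	single		P-loop-NTPase	1014
GkAMP	2.7.4.10	single		P-loop-NTPase	400
PyrH	2.7.4.22	single		P-loop-NTPase	590
Tmk	2.7.4.9	single		P-loop-NTPase	818
Cmk2	2.7.4.25	single		P-loop-NTPase	174
HydA	3.5.2.2	single			1032
PreA	1.3.1.2	subunit	dhp_dh		852
PreT	1.3.1.2	subunit	dhp_dh		693
PydA	1.3.1.1	single			998
PyrDo	1.3.3.1	single		FMN-oxidoreductase	387
PydC	3.5.1.6	single			675
ThyH	1.14.11.6	single			772
PsuG	4.2.1.70	single			411
DeoC	4.1.2.4	single			653
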