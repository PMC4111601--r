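gene	transcript	type	orientation	slr_2h	sd_2h	slr_4h	sd_4h	hash_4h	r_maturation	star_maturation	r_injury	star_injury	relationship
Axin2	NM_015732	mRNA	.	0.03	0.03	1.54	0.33	##	-0.83	**	0.88	.	.
Axin2	ENSMUST00000143435	lncRNA	antisense_overlap,intron_exon	-0.46	0.06	-0.26	0.03	#	0.28	.	-0.55	*	inverse
Igf1r	NM_010513	mRNA	.	0.07	0.01	0.25	0.03	##	0.54	*	0.97	.	.
Igf1r	AK040698	lncRNA	antisense_overlap,intron	1.34	0.31	1.31	0.26	.	-0.97	*	0.86	**	inconclusive
Ikbkb	NM_010546	mRNA	.	-0.49	0.09	0.10	0.01	##	0.87	**	0.16	.	.
Ikbkb	uc009ldv.1	lncRNA	sense_overlap,promoter	-2.05	2.06	-1.22	0.38	.	-0.04	.	-0.59	*	inconclusive
Prkcb	NM_008855	mRNA	.	-0.89	0.13	-0.23	0.03	##	0.95	**	-0.25	.	.
Prkcb	ENSMUST00000118119	lncRNA	sense_overlap,intron	-0.82	0.09	-0.49	0.05	##	0.94	*	-0.59	*	synergistic
Ralgds	NM_009058	mRNA	.	0.12	0.02	-0.25	0.05	##	-0.64	**	-0.65	.	.
Ralgds	uc008iyq.1	lncRNA	sense_overlap,intron_exon	1.23	0.15	0.41	0.06	##	-0.73	**	0.32	.	inconclusive
Cntn1	NM_001159648	mRNA	.	0.34	0.06	0.39	0.06	.	-0.78	*	0.91	**	.
Cntn1	AK004399	lncRNA	sense_overlap,three_prime_UTR	-0.33	0.03	-0.59	0.06	##	0.99	*	-1.00	*	inverse
Cntn1	AK140484	lncRNA	antisense_overlap,intron	0.09	0.01	-0.33	0.04	##	0.47	*	-0.75	.	inverse
Ncam1	NM_010875	mRNA	.	-1.38	0.21	-0.35	0.04	##	0.89	*	-0.25	.	.
Ncam1	uc009pjm.1	lncRNA	sense_overlap,promoter	-0.23	0.02	0.00	0.10	##	-0.92	*	-0.01	.	inconclusive
Ncam1	AK156022	lncRNA	antisense_overlap,intron	1.34	0.13	0.69	0.07	##	-0.41	.	0.52	*	inverse
Negr1	NM_001039094	mRNA	.	-0.39	0.04	-0.60	0.06	#	0.96	**	-0.99	*	.
Negr1	uc008ruz.1	lncRNA	bidirectional	-0.98	0.13	-0.70	0.08	.	0.50	*	-0.70	*	synergistic
Negr1	uc008rva.1	lncRNA	bidirectional	0.98	0.24	1.15	0.24	.	-0.53	*	0.93	**	inverse
Nrxn1	NM_020252	mRNA	.	-0.93	0.18	-0.14	0.02	##	0.21	**	-0.14	.	.
Nrxn1	uc008dwg.1	lncRNA	sense_overlap,intron	0.08	0.02	0.35	0.06	##	-0.48	.	0.95	.	inverse
Ntrk2	NM_008745	mRNA	.	-0.36	0.04	-0.25	0.02	#	0.96	**	-0.68	*	.
Ntrk2	AK021278	lncRNA	antisense_overlap,intron	0.16	0.02	-0.49	0.05	##	-0.87	**	-0.72	.	inconclusive
Sh2b3	NM_008507	mRNA	.	-1.50	0.34	-1.77	0.42	.	0.84	**	-0.93	**	.
Sh2b3	AK007127	lncRNA	antisense_overlap,first_intron	-0.06	0.02	0.37	0.07	##	-0.53	*	0.79	.	inverse
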