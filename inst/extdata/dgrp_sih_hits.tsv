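variant_id	minor	major	ref	maf	effect	p_value	nominated_gene	flybase_id	site_class
X_7450403_SNP	T	A	A	0.05051	-285.1	1.69E-06	n/a	n/a	Intergenic
2L_16836590_SNP	A	T	T	0.07368	-239.4	3.37E-06	CG13283	FBgn0032613	Non-Synonymous
X_18534233_SNP	G	A	A	0.08763	-231.7	6.18E-07	Rip11	FBgn0027335	Intron
3R_16606144_SNP	T	G	G	0.08763	-211.5	2.66E-06	syp	FBgn0038826	Intron
3R_16606324_SNP	A	G	G	0.08629	-206.7	5.57E-06	syp	FBgn0038826	Intron
X_5324045_SNP	T	A	A	0.1399	-174	5.05E-06	CG15784	FBgn0029766	Upstream
X_5324047_SNP	T	C	C	0.1378	-173.5	5.24E-06	CG15784	FBgn0029766	Upstream
3L_5158751_SNP	A	T	T	0.2254	-162.5	1.24E-06	shep	FBgn0052423	Intron
3L_16130048_SNP	T	C	C	0.1943	-160.2	2.96E-06	CG16838	FBgn0036574	Synonymous
3L_10188818_SNP	A	T	T	0.2051	-153.5	2.70E-06	ect	FBgn0000451	Intron
2L_6464258_SNP	A	T	T	0.2778	-138.5	5.18E-06	CG16947	FBgn0031816	Intron
3L_16128605_SNP	G	T	T	0.2712	-135.9	9.81E-06	CG16838	FBgn0036574	Synonymous
2R_16523641_SNP	A	C	C	0.4294	-131.9	7.83E-06	rig	FBgn0250850	Intron
2L_1699735_SNP	A	C	C	0.2826	-130.1	6.50E-06	chinmo	FBgn0086758	Downstream
2L_1699738_SNP	C	A	A	0.2842	-128.7	8.02E-06	chinmo	FBgn0086758	Downstream
X_6643090_INS	ACA	A	A	0.4913	123.9	7.23E-06	CG14439	FBgn0029898	Intron
2L_1788750_SNP	C	T	C	0.3966	129.2	3.66E-06	Gr22d	FBgn0045498	Downstream
2L_1788739_INS	T	TT	T	0.3946	129.7	2.44E-06	Gr22d	FBgn0045498	Downstream
2L_1788747_SNP	A	C	A	0.3978	132.5	1.70E-06	Gr22d	FBgn0045498	Downstream
3L_5503742_SNP	T	G	G	0.3743	132.7	3.63E-06	CG34342	FBgn0085371	Intron
2L_1788734_SNP	C	A	C	0.3944	133.4	1.68E-06	Gr22d	FBgn0045498	Downstream
3L_5503669_SNP	C	T	T	0.3487	135.2	2.31E-06	CG34342	FBgn0085371	Intron
3L_5505206_SNP	G	A	A	0.3333	146.8	1.33E-07	Lkr	FBgn0035610	Downstream
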