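probe_id	gene_symbols	mean_beta_case	mean_beta_control	beta_difference	p_value	q_fdr	genic_region	island_relation
cg26341831	TMEM63A	0.352	0.504	-0.152	9.04e-4	1.05e-2	Body	OpenSea
cg00446123	LIME1	0.340	0.478	-0.138	1.17e-3	1.18e-2	TSS200	N_Shore
cg27058497	RUNX3	0.314	0.450	-0.136	7.60e-4	9.88e-3	TSS200	OpenSea
cg08817540	HHLA2	0.390	0.524	-0.134	5.34e-4	8.92e-3	TSS1500	OpenSea
cg17587997	FYN	0.529	0.663	-0.134	8.66e-4	1.04e-2	5'UTR	OpenSea
cg00660167		0.754	0.581	0.174	5.58e-4	9.03e-3	intergenic	N_Shore
cg23189692	EIF4G1	0.652	0.486	0.166	5.10e-4	8.81e-3	Body	N_Shelf
cg17344770	C19orf71	0.674	0.511	0.163	2.00e-4	8.16e-3	TSS1500	OpenSea
cg07302959	FAM133B	0.664	0.503	0.161	9.04e-4	1.06e-2	Body	OpenSea
cg06633438	MLLT1	0.626	0.466	0.160	1.65e-4	8.16e-3	Body	Island
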