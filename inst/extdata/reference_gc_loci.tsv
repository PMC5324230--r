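probe_id	gene_symbols	mean_beta_hypersensitive	mean_beta_typical	mean_beta_control	genic_region
cg03484234	PNPLA4	0.595	0.525	0.536	TSS1500
cg04072270		0.651	0.708	0.715	intergenic
cg04438194		0.199	0.134	0.147	intergenic
cg05123845		0.546	0.601	0.605	intergenic
cg05252487	FAM24A	0.289	0.354	0.344	5'UTR
cg05376982	GSTM5	0.609	0.498	0.479	TSS200
cg11680055	GSTM1	0.440	0.318	0.276	TSS200
cg12042203		0.672	0.618	0.620	intergenic
cg14507445		0.833	0.776	0.773	intergenic
cg15059639	MYO3B	0.762	0.636	0.614	Body
cg19196401	DDO	0.520	0.615	0.598	Body
cg19251564		0.711	0.660	0.654	intergenic
cg19763428	PDE1C	0.420	0.362	0.349	Body
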