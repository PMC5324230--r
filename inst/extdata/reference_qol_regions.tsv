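gene	genic_region	r_squared	q_fdr	mean_beta_case	mean_beta_control	beta_difference
GRAMD1A	TSS1500	0.229	4.27e-3	0.357	0.265	0.092
ATP6V0E2	TSS200	0.226	4.27e-3	0.335	0.256	0.079
LOC401431	Body	0.224	4.27e-3	0.347	0.266	0.081
IL6R	Body	0.220	4.27e-3	0.380	0.304	0.076
LOC144571	TSS1500	0.220	4.27e-3	0.314	0.237	0.077
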