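snp	chr	gene	ea	nea	eaf	beta_exp	se_exp	pval_exp	beta_out	se_out	pval_out	proxy_out
rs34311906	4	ANK2	C	T	0.41	0.0677	0.0120	1.07E-08	NA	NA	NA	NA
rs6825454	4	FGA	C	T	0.31	0.0583	0.0096	7.43E-10	0.0047	0.0184	0.7961	rs56010410
rs11957829	5	LOC100505841	A	G	0.82	0.0677	0.0119	7.51E-09	0.0093	0.022	0.6732	NA
rs42039	7	CDK6	C	T	0.77	0.0677	0.0120	6.55E-09	0.039	0.0187	0.03639	NA
rs7304841	12	PDE3A	A	C	0.59	0.0488	0.0097	4.93E-08	-0.0142	0.0176	0.4183	NA
rs4932370	15	FURIN-FES	A	G	0.33	0.0488	0.0097	2.88E-08	-0.0071	0.0171	0.6793	NA
rs11867415	17	PRPF8	G	A	0.18	0.0862	0.0163	4.81E-08	-0.0392	0.0347	0.258	NA
rs2229383	19	ILF3-SLC44A2	T	G	0.65	0.0488	0.0097	4.72E-08	0.0158	0.0169	0.3508	NA
rs635634	9	ABO	T	C	0.19	0.0770	0.0142	9.18E-09	-0.0055	0.0195	0.7793	NA
rs2005108	11	MMP12	T	C	0.12	0.0770	0.0142	3.33E-08	-0.0003	0.0231	0.9888	NA
rs3184504	12	SH2B3	T	C	0.45	0.0770	0.0094	2.17E-14	-0.0252	0.0159	0.1134	NA
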