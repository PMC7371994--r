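snp	chr	gene	ea	nea	eaf	beta_exp	se_exp	pval_exp	beta_out	se_out	pval_out	proxy_out
rs146390073	1	RGS7	T	C	0.02	0.6678	0.1205	2.20E-08	NA	NA	NA	NA
rs6891174	5	NKX2-5	A	G	0.35	0.1044	0.0206	5.82E-09	-0.0021	0.017	0.9006	NA
rs13143308	4	PITX2	T	G	0.34	0.2776	0.0193	1.86E-47	-0.0128	0.0188	0.4972	NA
rs12932445	16	ZFHX3	C	T	0.21	0.1823	0.0213	6.86E-18	-0.0261	0.0216	0.2272	NA
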