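snp	chr	gene	ea	nea	eaf	beta_exp	se_exp	pval_exp	beta_out	se_out	pval_out	proxy_out
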