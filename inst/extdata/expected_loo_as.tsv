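excluded_snp	ivw_beta	ivw_p	wmr_beta	wmr_p	egger_beta	egger_p	intercept_beta	intercept_p
rs880315	-0.027	0.838	-0.192	0.211	-1.349	0.105	0.074	0.108
rs12037987	-0.037	0.778	-0.167	0.259	-1.440	0.103	0.078	0.109
rs16896398	-0.030	0.822	-0.193	0.197	-1.527	0.070	0.085	0.073
rs7859727	-0.093	0.443	-0.211	0.147	-1.097	0.177	0.057	0.212
rs2295786	0.011	0.926	-0.152	0.312	-1.432	0.046	0.081	0.041
rs35436	-0.061	0.640	-0.193	0.196	-1.299	0.152	0.070	0.168
rs9526212	-0.008	0.949	-0.152	0.325	-1.232	0.139	0.068	0.138
rs8103309	-0.085	0.487	-0.198	0.175	-1.150	0.153	0.060	0.181
rs1052053	0.010	0.939	-0.144	0.357	-1.133	0.197	0.063	0.189
rs4959130	0.005	0.971	-0.152	0.319	-1.240	0.283	0.067	0.279
rs12445022	-0.109	0.348	-0.225	0.119	-1.485	0.030	0.077	0.042
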