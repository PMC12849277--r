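protein	cluster	beta_step1	beta_step2	total	printed_pct
MET	risk_increasing	-0.101351	-0.148	1.27	1.18
MET	highly_protective	0.195946	-0.148	-1.92	1.51
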