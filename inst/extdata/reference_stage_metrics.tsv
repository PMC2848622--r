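dictionary	stage	precision	recall	f_reported
chemspider	unprocessed	0.43	0.19	0.26
chemspider	filtered	0.81	0.19	0.31
chemspider	frequent_terms	0.85	0.19	0.31
chemspider	disambiguation	0.87	0.19	0.31
chemlist	unprocessed	0.20	0.47	0.28
chemlist	filtered	0.39	0.46	0.42
chemlist	frequent_terms	0.55	0.46	0.50
chemlist	disambiguation	0.67	0.40	0.50
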