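dictionary	category	count	total_fp	pct_reported
chemspider	partial_match	21	33	64
chemspider	annotation_error	11	33	33
chemspider	out_of_corpus_scope	1	33	3
chemspider	not_a_chemical	0	33	0
chemlist	partial_match	96	232	41
chemlist	annotation_error	29	232	13
chemlist	out_of_corpus_scope	79	232	34
chemlist	not_a_chemical	28	232	12
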