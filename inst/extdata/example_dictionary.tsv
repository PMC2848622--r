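concept_id	term	preferred	cas	inchi	xrefs	source	formula	origin	status	removal_reason
EX001	aspirin	1	50-78-2	InChI=1S/C9H8O4/c1-6(10)13-8-5-3-2-4-7(8)9(11)12/h2-5H,1H3,(H,11,12)	chebi:15365	example	C9H8O4	source	active
EX001	acetylsalicylic acid	0	50-78-2	InChI=1S/C9H8O4/c1-6(10)13-8-5-3-2-4-7(8)9(11)12/h2-5H,1H3,(H,11,12)	chebi:15365	example	C9H8O4	source	active
EX001	acid, acetylsalicylic	0	50-78-2	InChI=1S/C9H8O4/c1-6(10)13-8-5-3-2-4-7(8)9(11)12/h2-5H,1H3,(H,11,12)	chebi:15365	example	C9H8O4	source	active
EX002	sodium chloride	1	7647-14-5		chebi:26710	example	NaCl	source	active
EX002	NaCl	0	7647-14-5		chebi:26710	example	NaCl	source	active
EX003	copper sulfate pentahydrate	1	7758-99-8		chebi:31440	example	CuSO4·5H2O	source	active
EX004	gamma-aminobutyric acid (GABA)	1	56-12-2		chebi:16865	example	C4H9NO2	source	active
EX005	Ringer's lactate	1			example:rl	example		source	active
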