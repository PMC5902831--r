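variant_id	chrom	pos	ref	alt	qual	call_rate	is_indel	indel_len	coding	consequence	gene_id	sift	provean	aa_pos	aa_len	ortho11	rnacov	ac_WA	an_WA	nhom_WA	ac_W1	an_W1	nhom_W1
v1	1	100500	C	T	50	0.95	FALSE	NA	TRUE	stop_gained	GENE_LETHAL1	NA	NA	120	400	TRUE	500	3	140	0	0	200	0
v2	1	220000	G	A	48	0.96	FALSE	NA	TRUE	splice_donor	GENE_LETHAL2	NA	NA	NA	NA	TRUE	350	2	140	0	1	200	0
v3	1	100800	A	G	52	0.97	FALSE	NA	TRUE	missense	GENE_LETHAL1	0.2	-1.1	88	400	TRUE	500	4	140	0	2	200	0
v4	1	221500	T	C	55	0.98	FALSE	NA	TRUE	missense	GENE_LETHAL2	0.01	-6.2	210	630	TRUE	350	5	140	1	0	200	0
v5	2	50400	A	AG	47	0.93	TRUE	1	TRUE	frameshift	GENE_OTHER	NA	NA	33	250	TRUE	800	2	140	0	0	200	0
v6	1	100950	G	A	60	0.99	FALSE	NA	TRUE	synonymous	GENE_LETHAL1	NA	NA	150	400	TRUE	500	6	140	0	3	200	0
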