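##fileformat=VCFv4.2
##contig=<ID=1>
##INFO=<ID=CALLRATE,Number=1,Type=Float,Description="Site call rate">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	998	S1	C	T	50	PASS	CALLRATE=0.95
1	1000	I1	AT	A	50	PASS	CALLRATE=0.95
1	1002	S2	G	A	50	PASS	CALLRATE=0.95
1	5000	S3	A	G	15	PASS	CALLRATE=0.95
1	6000	S4	T	C	50	PASS	CALLRATE=0.6
1	10000	S5	A	G	50	PASS	CALLRATE=0.95
1	20000	S6	C	T	48	PASS	CALLRATE=0.92
1	30000	S7	G	A	60	PASS	CALLRATE=0.99
1	40000	S8	T	C	55	PASS	CALLRATE=0.97
1	50000	S9	A	C	45	PASS	CALLRATE=0.9
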