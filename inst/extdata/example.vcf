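##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4	S5
chr1	100	rs1	A	G	.	PASS	.	GT	0/0	0/1	1/1	0/0	0/1
chr1	200	rs2	C	T	.	PASS	.	GT	0|1	0/0	0/0	1/1	0/1
chr1	300	rs3	G	A	.	PASS	.	GT	1/1	0/1	0/0	0/1	0/0
chr1	400	rs4	T	C	.	PASS	.	GT	./.	0/0	0/1	0/0	1/1
chr2	150	rs5	A	C,T	.	PASS	.	GT	0/1	0/2	1/1	0/0	0/1
chr2	250	rs6	G	C	.	PASS	.	GT	0/0	0/0	0/1	0/1	1/1
chr2	350	rs7	C	G	.	PASS	.	GT	0/1	1/0	0/0	1/1	0/0
chr2	450	rs8	T	A	.	PASS	.	GT	0/0	0/1	0/1	0/0	0/0
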