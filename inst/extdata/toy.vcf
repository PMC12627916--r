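##fileformat=VCFv4.2
##contig=<ID=c1,length=400>
##contig=<ID=c2,length=300>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3
c1	101	.	A	G	.	PASS	.	GT	0/0	0/1	1/1
c1	120	.	C	T	.	PASS	.	GT	0/1	0/1	./.
c1	133	.	G	A,T	.	PASS	.	GT	0/2	1/2	0/0
c1	150	.	T	C	.	PASS	.	GT	1|0	0/0	0/0
c1	188	.	A	C	.	PASS	.	GT	0/0	0/0	1/1
c1	240	.	G	T	.	PASS	.	GT	0/1	./.	0/1
c2	55	.	C	G	.	PASS	.	GT	0/0	0/1	1/1
c2	80	.	T	A	.	PASS	.	GT	1/1	0/0	0/1
c2	143	.	A	G	.	PASS	.	GT	0/1	0/1	0/0
c2	201	.	G	C	.	PASS	.	GT	0/0	1/1	./.
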