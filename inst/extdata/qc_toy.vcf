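##fileformat=VCFv4.2
##source=handmade-toy
##contig=<ID=contig1,length=10000>
##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10
contig1	100	.	A	G	.	PASS	MQ=60	GT:DP	0/1:10	0/1:10	0/1:10	0/1:10	0/1:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10
contig1	200	.	A	C,T	.	PASS	MQ=60	GT:DP	0/0:10	0/0:10	1/2:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	1/1:10
contig1	300	.	G	T	.	PASS	MQ=19.9	GT:DP	0/1:10	0/1:10	0/1:10	0/1:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10
contig1	400	.	C	T	.	PASS	MQ=60	GT:DP	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10
contig1	500	.	T	A	.	PASS	MQ=60	GT:DP	./.:10	./.:10	0/1:10	0/1:10	0/1:10	0/1:10	0/0:10	0/0:10	0/0:10	0/0:10
contig1	600	.	A	C	.	PASS	MQ=60	GT:DP	0/1:2	0/1:2	0/1:10	0/1:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10
contig1	700	.	G	A	.	PASS	MQ=60	GT:DP	0/1:10	0/1:10	0/1:10	1/1:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10
contig1	800	.	C	G	.	PASS	MQ=60	GT:DP	0/0:10	0/0:10	0/0:10	0/0:10	0/0:10	1/1:10	1/1:10	1/1:10	1/1:10	1/1:10
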