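##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Predicted consequence">
##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1
chrX	1601004	.	C	G	50	PASS	GENE=AKAP17A;CSQ=missense variant;POPAF=0.54	GT:DP:AD	1:100:80,20
X	2700000	.	T	A	60	PASS	GENE=SHOX;CSQ=synonymous;POPAF=0.20	GT:DP:AD	1:60:0,60
1	1000	.	G	A	30	PASS	GENE=DNMT3A;CSQ=stop gained	GT:DP:AD	0/1:50:25,25
22	32857305	rs11547635	C	T	99	PASS	GENE=TIMP3;CSQ=synonymous variant;POPAF=0.09	GT:DP:AD	1/1:80:2,78
2	5000	.	A	C	10	PASS	GENE=MSH2;CSQ=missense	GT	0/1
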