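sample_id,chrom,pos,ref,alt,gene,consequence,depth,vaf,call_quality,pop_af,genotype
S1,X,1601004,C,G,AKAP17A,missense,100,0.2,50,0.54,hem
S1,X,2700000,T,A,SHOX,synonymous,60,1,60,0.2,hem
S1,22,32857305,C,T,TIMP3,stop gained,80,0.975,99,0.09,hom
S2,X,1601004,C,G,AKAP17A,missense,88,0.95,61,0.54,hem
S2,X,49028726,G,A,CACNA1F,frameshift variant,45,0.12,33,0.15,hem
S2,7,140753336,A,T,BRAF,missense variant,120,0.48,92,,het
S3,X,70443591,C,T,MED12,inframe deletion,72,0.96,70,0.41,hem
S3,X,153296777,G,C,MECP2,unusual annotation,55,0.93,48,0.88,hem
S3,1,11794419,T,C,MTHFR,synonymous variant,64,0.52,58,0.31,het
S3,2,47403191,A,G,MSH2,stop gained,39,0.08,21,0.12,het
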