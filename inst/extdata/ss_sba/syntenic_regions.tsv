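chrom	direction	n_regions	sum_query_bp	sum_ref_bp
chr1	expanded	2	228757	438099
chr1	contracted	2	246930	170629
chr2	expanded	7	843489	1530484
chr2	contracted	3	390747	307693
chr3	expanded	3	300722	649695
chr3	contracted	5	623310	501139
chr4	expanded	2	228311	542706
chr4	contracted	1	129840	60597
chr5	expanded	1	105911	192480
chr5	contracted	1	188640	93686
chr6	expanded	0	0	0
chr6	contracted	2	247660	68939
chr7	expanded	1	44210	296520
chr7	contracted	0	0	0
chr8	expanded	2	266020	341742
chr8	contracted	1	125996	124114
chr9	expanded	2	221580	423004
chr9	contracted	1	114955	91453
chr10	expanded	2	184310	374313
chr10	contracted	4	502882	283520
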