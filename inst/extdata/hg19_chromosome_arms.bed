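chr1	0	121535434	1p
chr1	124535434	249250621	1q
chr2	0	92326171	2p
chr2	95326171	243199373	2q
chr3	0	90504854	3p
chr3	93504854	198022430	3q
chr4	0	49660117	4p
chr4	52660117	191154276	4q
chr5	0	46405641	5p
chr5	49405641	180915260	5q
chr6	0	58830166	6p
chr6	61830166	171115067	6q
chr7	0	58054331	7p
chr7	61054331	159138663	7q
chr8	0	43838887	8p
chr8	46838887	146364022	8q
chr9	0	47367679	9p
chr9	50367679	141213431	9q
chr10	0	39254935	10p
chr10	42254935	135534747	10q
chr11	0	51644205	11p
chr11	54644205	135006516	11q
chr12	0	34856694	12p
chr12	37856694	133851895	12q
chr13	0	16000000	13p
chr13	19000000	115169878	13q
chr14	0	16000000	14p
chr14	19000000	107349540	14q
chr15	0	17000000	15p
chr15	20000000	102531392	15q
chr16	0	35335801	16p
chr16	38335801	90354753	16q
chr17	0	22263006	17p
chr17	25263006	81195210	17q
chr18	0	15460898	18p
chr18	18460898	78077248	18q
chr19	0	24681782	19p
chr19	27681782	59128983	19q
chr20	0	26369569	20p
chr20	29369569	63025520	20q
chr21	0	11288129	21p
chr21	14288129	48129895	21q
chr22	0	13000000	22p
chr22	16000000	51304566	22q
chrX	0	58632012	Xp
chrX	61632012	155270560	Xq
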