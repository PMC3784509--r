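label	start	end	region_class	coding_strand	frame
TRNF	577	647	tRNA	H	0
RNR1	648	1601	rRNA	H	0
TRNV	1602	1670	tRNA	H	0
RNR2	1671	3229	rRNA	H	0
TRNL1	3230	3304	tRNA	H	0
ND1	3307	4262	protein_coding	H	0
TRNI	4263	4331	tRNA	H	0
TRNQ	4329	4400	tRNA	L	0
TRNM	4402	4469	tRNA	H	0
ND2	4470	5511	protein_coding	H	0
TRNW	5512	5579	tRNA	H	0
TRNA	5587	5655	tRNA	L	0
TRNN	5657	5729	tRNA	L	0
TRNC	5761	5826	tRNA	L	0
TRNY	5826	5891	tRNA	L	0
CO1	5904	7445	protein_coding	H	0
TRNS1	7446	7514	tRNA	L	0
TRND	7518	7585	tRNA	H	0
CO2	7586	8269	protein_coding	H	0
TRNK	8295	8364	tRNA	H	0
ATP8	8366	8572	protein_coding	H	0
ATP6	8527	9207	protein_coding	H	0
CO3	9207	9990	protein_coding	H	0
TRNG	9991	10058	tRNA	H	0
ND3	10059	10404	protein_coding	H	0
TRNR	10405	10469	tRNA	H	0
ND4L	10470	10766	protein_coding	H	0
ND4	10760	12137	protein_coding	H	0
TRNH	12138	12206	tRNA	H	0
TRNS2	12207	12265	tRNA	H	0
TRNL2	12266	12336	tRNA	H	0
ND5	12337	14148	protein_coding	H	0
ND6	14149	14673	protein_coding	L	0
TRNE	14674	14742	tRNA	L	0
CYB	14747	15887	protein_coding	H	0
TRNT	15888	15953	tRNA	H	0
TRNP	15956	16023	tRNA	L	0
DLOOP	16024	576	control	H	0
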