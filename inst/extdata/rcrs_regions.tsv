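name	start	end	category	complex	strand
mtCTR_a	16024	16569	control-region	none	.
mtCTR_b	1	576	control-region	none	.
HVS1	16024	16383	HVS1	none	.
HVS2	57	372	HVS2	none	.
HVS3	438	574	HVS3	none	.
MT-TF	577	647	tRNA-gene	none	H
MT-RNR1	648	1601	rRNA-gene	none	H
MT-TV	1602	1670	tRNA-gene	none	H
MT-RNR2	1671	3229	rRNA-gene	none	H
MT-TL1	3230	3304	tRNA-gene	none	H
MT-ND1	3307	4262	protein-gene	I	H
MT-TI	4263	4331	tRNA-gene	none	H
MT-TQ	4329	4400	tRNA-gene	none	L
MT-TM	4402	4469	tRNA-gene	none	H
MT-ND2	4470	5511	protein-gene	I	H
MT-TW	5512	5579	tRNA-gene	none	H
MT-TA	5587	5655	tRNA-gene	none	L
MT-TN	5657	5729	tRNA-gene	none	L
OriL	5721	5798	origin	none	.
MT-TC	5761	5826	tRNA-gene	none	L
MT-TY	5826	5891	tRNA-gene	none	L
MT-CO1	5904	7445	protein-gene	IV	H
MT-TS1	7446	7514	tRNA-gene	none	L
MT-TD	7518	7585	tRNA-gene	none	H
MT-CO2	7586	8269	protein-gene	IV	H
MT-TK	8295	8364	tRNA-gene	none	H
MT-ATP8	8366	8572	protein-gene	V	H
MT-ATP6	8527	9207	protein-gene	V	H
MT-CO3	9207	9990	protein-gene	IV	H
MT-TG	9991	10058	tRNA-gene	none	H
MT-ND3	10059	10404	protein-gene	I	H
MT-TR	10405	10469	tRNA-gene	none	H
MT-ND4L	10470	10766	protein-gene	I	H
MT-ND4	10760	12137	protein-gene	I	H
MT-TH	12138	12206	tRNA-gene	none	H
MT-TS2	12207	12265	tRNA-gene	none	H
MT-TL2	12266	12336	tRNA-gene	none	H
MT-ND5	12337	14148	protein-gene	I	H
MT-ND6	14149	14673	protein-gene	I	L
MT-TE	14674	14742	tRNA-gene	none	L
MT-CYB	14747	15887	protein-gene	III	H
MT-TT	15888	15953	tRNA-gene	none	H
MT-TP	15956	16023	tRNA-gene	none	L
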