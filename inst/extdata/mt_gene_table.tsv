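feature	start	end	kind	strand
tRNA-Phe	577	647	tRNA	H
12S-rRNA	648	1601	rRNA	H
tRNA-Val	1602	1670	tRNA	H
16S-rRNA	1671	3229	rRNA	H
tRNA-Leu-UUR	3230	3304	tRNA	H
ND1	3307	4262	protein	H
tRNA-Ile	4263	4331	tRNA	H
tRNA-Gln	4329	4400	tRNA	L
tRNA-Met	4402	4469	tRNA	H
ND2	4470	5511	protein	H
tRNA-Trp	5512	5579	tRNA	H
tRNA-Ala	5587	5655	tRNA	L
tRNA-Asn	5657	5729	tRNA	L
tRNA-Cys	5761	5826	tRNA	L
tRNA-Tyr	5826	5891	tRNA	L
CO1	5904	7445	protein	H
tRNA-Ser-UCN	7446	7514	tRNA	L
tRNA-Asp	7518	7585	tRNA	H
CO2	7586	8269	protein	H
tRNA-Lys	8295	8364	tRNA	H
ATP8	8366	8572	protein	H
ATP6	8527	9207	protein	H
CO3	9207	9990	protein	H
tRNA-Gly	9991	10058	tRNA	H
ND3	10059	10404	protein	H
tRNA-Arg	10405	10469	tRNA	H
ND4L	10470	10766	protein	H
ND4	10760	12137	protein	H
tRNA-His	12138	12206	tRNA	H
tRNA-Ser-AGY	12207	12265	tRNA	H
tRNA-Leu-CUN	12266	12336	tRNA	H
ND5	12337	14148	protein	H
ND6	14149	14673	protein	L
tRNA-Glu	14674	14742	tRNA	L
CYB	14747	15887	protein	H
tRNA-Thr	15888	15953	tRNA	H
tRNA-Pro	15956	16023	tRNA	L
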