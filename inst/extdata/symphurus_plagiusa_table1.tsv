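name	from	to	strand	intergenic
tRNA-Phe	1	69	H	0
12S	70	1016	H	0
tRNA-Val	1017	1086	H	0
16S	1087	2793	H	0
tRNA-Leu^UUA	2794	2866	H	0
ND1	2867	3841	H	2
tRNA-Ile	3844	3913	H	-2
tRNA-Gln	3912	3982	L	-1
tRNA-Met	3982	4050	H	124
ND2	4175	5227	H	42
tRNA-Trp	5270	5339	H	0
tRNA-Ala	5340	5408	L	0
tRNA-Asn	5409	5479	L	2
tRNA-Cys	5482	5546	L	3
tRNA-Tyr	5550	5616	L	1
COI	5618	7168	H	0
tRNA-Ser^UCA	7169	7239	L	19
tRNA-Asp	7259	7327	H	4
COII	7332	7925	H	96
tRNA-Lys	8022	8097	H	1
ATP8	8099	8266	H	-10
ATP6	8257	8940	H	2
COIII	8943	9731	H	65
tRNA-Gly	9797	9864	H	0
ND3	9865	10215	H	-2
tRNA-Arg	10214	10282	H	0
ND4L	10283	10579	H	-7
ND4	10573	11953	H	0
tRNA-His	11954	12022	H	0
tRNA-Ser^UGC	12023	12090	H	2
tRNA-Leu^GUA	12093	12164	H	0
ND5	12165	13985	H	-4
ND6	13982	14500	L	0
tRNA-Glu	14501	14569	L	2
Cytb	14572	15711	H	1
tRNA-Thr	15713	15781	H	-1
tRNA-Pro	15781	15849	L	0
O_L-like Seq.	16983	17034	L	NA
D-loop	15850	17040	H	0
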