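name	from	to	strand	intergenic
tRNA-Phe	1	71	H	0
12S	72	1020	H	65
16S	1086	2796	H	98
tRNA-Met	2895	2964	H	100
tRNA-Val	3065	3136	H	31
tRNA-Leu^UUA	3168	3240	H	0
ND1	3241	4212	H	7
tRNA-Ile	4220	4289	H	-2
tRNA-Gln	4288	4358	L	117
ND2	4476	5522	H	37
tRNA-Trp	5560	5628	H	0
tRNA-Ala	5629	5697	L	0
tRNA-Asn	5698	5770	L	3
tRNA-Cys	5774	5839	L	4
tRNA-Tyr	5844	5910	L	10
COI	5921	7471	H	0
tRNA-Ser^UCA	7472	7542	L	19
tRNA-Asp	7562	7630	H	5
COII	7636	8326	H	0
tRNA-Lys	8327	8400	H	2
ATP8	8403	8570	H	-10
ATP6	8561	9244	H	-1
COIII	9244	10029	H	-1
tRNA-Gly	10029	10096	H	0
ND3	10097	10447	H	-2
tRNA-Arg	10446	10514	H	0
ND4L	10515	10811	H	-7
ND4	10805	12184	H	1
tRNA-His	12186	12253	H	0
tRNA-Ser^UGC	12254	12321	H	2
tRNA-Leu^GUA	12324	12397	H	0
ND5	12398	14233	H	4
ND6	14238	14756	L	0
tRNA-Glu	14757	14825	L	3
Cytb	14829	15969	H	0
tRNA-Thr	15970	16042	H	-1
tRNA-Pro	16042	16110	L	0
D-loop	16111	17498	H	0
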