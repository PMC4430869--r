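# mitotdrl gene synonym table, version 1
# synonym <TAB> canonical ; lookup is case-insensitive after stripping
# whitespace and punctuation, so one pretty spelling per synonym suffices.
synonym	canonical
tRNA-Phe	F
trnF	F
tRNA-Val	V
trnV	V
tRNA-Leu^UUA	L1
tRNA-Leu (UUR)	L1
tRNA-Leu(UUR)	L1
trnL1	L1
trnL(UUR)	L1
tRNA-Leu^GUA	L2
tRNA-Leu (CUN)	L2
tRNA-Leu(CUN)	L2
trnL2	L2
trnL(CUN)	L2
tRNA-Ile	I
trnI	I
tRNA-Gln	Q
trnQ	Q
tRNA-Met	M
trnM	M
tRNA-Trp	W
trnW	W
tRNA-Ala	A
trnA	A
tRNA-Asn	N
trnN	N
tRNA-Cys	C
trnC	C
tRNA-Tyr	Y
trnY	Y
tRNA-Ser^UCA	S1
tRNA-Ser (UCN)	S1
tRNA-Ser(UCN)	S1
trnS1	S1
trnS(UCN)	S1
tRNA-Ser^UGC	S2
tRNA-Ser (AGY)	S2
tRNA-Ser(AGY)	S2
trnS2	S2
trnS(AGY)	S2
tRNA-Asp	D
trnD	D
tRNA-Lys	K
trnK	K
tRNA-Gly	G
trnG	G
tRNA-Arg	R
trnR	R
tRNA-His	H
trnH	H
tRNA-Glu	E
trnE	E
tRNA-Thr	T
trnT	T
tRNA-Pro	P
trnP	P
12S	r12S
12S rRNA	r12S
12S ribosomal RNA	r12S
s-rRNA	r12S
rrnS	r12S
small subunit ribosomal RNA	r12S
16S	r16S
16S rRNA	r16S
16S ribosomal RNA	r16S
l-rRNA	r16S
rrnL	r16S
large subunit ribosomal RNA	r16S
ND1	ND1
NADH dehydrogenase subunit 1	ND1
nad1	ND1
ND2	ND2
NADH dehydrogenase subunit 2	ND2
nad2	ND2
ND3	ND3
NADH dehydrogenase subunit 3	ND3
nad3	ND3
ND4	ND4
NADH dehydrogenase subunit 4	ND4
nad4	ND4
ND4L	ND4L
NADH dehydrogenase subunit 4L	ND4L
nad4l	ND4L
ND5	ND5
NADH dehydrogenase subunit 5	ND5
nad5	ND5
ND6	ND6
NADH dehydrogenase subunit 6	ND6
nad6	ND6
COI	COI
CO1	COI
COX1	COI
cox1	COI
cytochrome c oxidase subunit I	COI
cytochrome c oxidase subunit 1	COI
COII	COII
CO2	COII
COX2	COII
cytochrome c oxidase subunit II	COII
cytochrome c oxidase subunit 2	COII
COIII	COIII
CO3	COIII
COX3	COIII
cytochrome c oxidase subunit III	COIII
cytochrome c oxidase subunit 3	COIII
ATP6	ATP6
ATPase 6	ATP6
ATP synthase F0 subunit 6	ATP6
ATP8	ATP8
ATPase 8	ATP8
ATP synthase F0 subunit 8	ATP8
Cytb	Cytb
CYTB	Cytb
cob	Cytb
cytochrome b	Cytb
D-loop	CR
control region	CR
CR	CR
putative control region	CR
OL	OL
O_L	OL
L-strand origin	OL
origin of L-strand replication	OL
rep_origin	OL
O_L-like Seq.	OL_LIKE
OL-like	OL_LIKE
O_L-like	OL_LIKE
O_L-like structure	OL_LIKE
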