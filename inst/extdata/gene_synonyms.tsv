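synonym	canonical
COX1	cox1
COI	cox1
CO1	cox1
cytochrome c oxidase subunit 1	cox1
cytochrome c oxidase subunit I	cox1
cytochrome oxidase subunit 1	cox1
COX2	cox2
COII	cox2
CO2	cox2
cytochrome c oxidase subunit 2	cox2
cytochrome c oxidase subunit II	cox2
cytochrome oxidase subunit 2	cox2
COX3	cox3
COIII	cox3
CO3	cox3
cytochrome c oxidase subunit 3	cox3
cytochrome c oxidase subunit III	cox3
cytochrome oxidase subunit 3	cox3
ND1	nad1
NADH1	nad1
nad1	nad1
NADH dehydrogenase subunit 1	nad1
ND2	nad2
NADH2	nad2
nad2	nad2
NADH dehydrogenase subunit 2	nad2
ND3	nad3
NADH3	nad3
nad3	nad3
NADH dehydrogenase subunit 3	nad3
ND4	nad4
NADH4	nad4
nad4	nad4
NADH dehydrogenase subunit 4	nad4
ND5	nad5
NADH5	nad5
nad5	nad5
NADH dehydrogenase subunit 5	nad5
ND6	nad6
NADH6	nad6
nad6	nad6
NADH dehydrogenase subunit 6	nad6
ND4L	nad4l
nad4l	nad4l
NADH dehydrogenase subunit 4L	nad4l
ATP6	atp6
ATPase6	atp6
ATP synthase F0 subunit 6	atp6
ATP8	atp8
ATPase8	atp8
ATP synthase F0 subunit 8	atp8
CYTB	cob
cob	cob
cytochrome b	cob
16S	rrnL
16S ribosomal RNA	rrnL
l-rRNA	rrnL
large subunit ribosomal RNA	rrnL
rrnL	rrnL
16S rRNA	rrnL
12S	rrnS
12S ribosomal RNA	rrnS
s-rRNA	rrnS
small subunit ribosomal RNA	rrnS
rrnS	rrnS
12S rRNA	rrnS
tRNA-Ala	trnA
trnA	trnA
tRNA-Arg	trnR
trnR	trnR
tRNA-Asn	trnN
trnN	trnN
tRNA-Asp	trnD
trnD	trnD
tRNA-Cys	trnC
trnC	trnC
tRNA-Gln	trnQ
trnQ	trnQ
tRNA-Glu	trnE
trnE	trnE
tRNA-Gly	trnG
trnG	trnG
tRNA-His	trnH
trnH	trnH
tRNA-Ile	trnI
trnI	trnI
tRNA-Lys	trnK
trnK	trnK
tRNA-Met	trnM
trnM	trnM
tRNA-Phe	trnF
trnF	trnF
tRNA-Pro	trnP
trnP	trnP
tRNA-Thr	trnT
trnT	trnT
tRNA-Trp	trnW
trnW	trnW
tRNA-Tyr	trnY
trnY	trnY
tRNA-Val	trnV
trnV	trnV
tRNA-Leu	trnL?
trnL	trnL?
tRNA-Ser	trnS?
trnS	trnS?
tRNA-Leu(CUN)	trnL1
trnL1	trnL1
trnL(CUN)	trnL1
tRNA-Leu(UUR)	trnL2
trnL2	trnL2
trnL(UUR)	trnL2
tRNA-Ser(AGN)	trnS1
trnS1	trnS1
trnS(AGN)	trnS1
tRNA-Ser(UCN)	trnS2
trnS2	trnS2
trnS(UCN)	trnS2
CR	CR
D-loop	CR
control region	CR
A+T-rich region	CR
putative control region	CR
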