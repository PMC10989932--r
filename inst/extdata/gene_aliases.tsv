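Old Name	New Name
cox1	cox1
COI	cox1
CO1	cox1
COXI	cox1
cytochrome c oxidase subunit 1	cox1
cytochrome c oxidase subunit I	cox1
cytochrome oxidase subunit 1	cox1
cox2	cox2
COII	cox2
CO2	cox2
COXII	cox2
cytochrome c oxidase subunit 2	cox2
cytochrome c oxidase subunit II	cox2
cytochrome oxidase subunit 2	cox2
cox3	cox3
COIII	cox3
CO3	cox3
COXIII	cox3
cytochrome c oxidase subunit 3	cox3
cytochrome c oxidase subunit III	cox3
cytochrome oxidase subunit 3	cox3
cob	cob
CYTB	cob
cytochrome b	cob
cytochrome b apoenzyme	cob
cb	cob
nad1	nad1
ND1	nad1
NDH1	nad1
NADH dehydrogenase subunit 1	nad1
nadh1	nad1
nad2	nad2
ND2	nad2
NDH2	nad2
NADH dehydrogenase subunit 2	nad2
nadh2	nad2
nad3	nad3
ND3	nad3
NDH3	nad3
NADH dehydrogenase subunit 3	nad3
nadh3	nad3
nad4	nad4
ND4	nad4
NDH4	nad4
NADH dehydrogenase subunit 4	nad4
nadh4	nad4
nad5	nad5
ND5	nad5
NDH5	nad5
NADH dehydrogenase subunit 5	nad5
nadh5	nad5
nad6	nad6
ND6	nad6
NDH6	nad6
NADH dehydrogenase subunit 6	nad6
nadh6	nad6
nad4L	nad4L
ND4L	nad4L
NADH dehydrogenase subunit 4L	nad4L
nadh4l	nad4L
atp6	atp6
ATPase6	atp6
ATP synthase F0 subunit 6	atp6
ATP synthase subunit 6	atp6
atp8	atp8
ATPase8	atp8
ATP synthase F0 subunit 8	atp8
ATP synthase subunit 8	atp8
rrnL	rrnL
16S	rrnL
16S rRNA	rrnL
16S ribosomal RNA	rrnL
l-rRNA	rrnL
large subunit ribosomal RNA	rrnL
lsu rRNA	rrnL
rrn16	rrnL
rrnS	rrnS
12S	rrnS
12S rRNA	rrnS
12S ribosomal RNA	rrnS
s-rRNA	rrnS
small subunit ribosomal RNA	rrnS
ssu rRNA	rrnS
rrn12	rrnS
trnA	trnA
tRNA-Ala	trnA
trnR	trnR
tRNA-Arg	trnR
trnN	trnN
tRNA-Asn	trnN
trnD	trnD
tRNA-Asp	trnD
trnC	trnC
tRNA-Cys	trnC
trnQ	trnQ
tRNA-Gln	trnQ
trnE	trnE
tRNA-Glu	trnE
trnG	trnG
tRNA-Gly	trnG
trnH	trnH
tRNA-His	trnH
trnI	trnI
tRNA-Ile	trnI
trnL	trnL
tRNA-Leu	trnL
trnK	trnK
tRNA-Lys	trnK
trnM	trnM
tRNA-Met	trnM
trnF	trnF
tRNA-Phe	trnF
trnP	trnP
tRNA-Pro	trnP
trnS	trnS
tRNA-Ser	trnS
trnT	trnT
tRNA-Thr	trnT
trnW	trnW
tRNA-Trp	trnW
trnY	trnY
tRNA-Tyr	trnY
trnV	trnV
tRNA-Val	trnV
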