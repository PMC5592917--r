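gene	class	strand	length
trnI	trna	+	69
trnQ	trna	-	69
trnM	trna	+	68
ND2	protein_coding	+	1023
trnW	trna	+	68
trnC	trna	-	66
trnY	trna	-	67
COX1	protein_coding	+	1536
trnL2	trna	+	67
COX2	protein_coding	+	684
trnK	trna	+	70
trnD	trna	+	68
ATP8	protein_coding	+	159
ATP6	protein_coding	+	678
COX3	protein_coding	+	786
trnG	trna	+	66
ND3	protein_coding	+	354
trnA	trna	+	67
trnR	trna	+	66
trnN	trna	+	68
trnS1	trna	+	68
trnE	trna	+	67
trnF	trna	-	68
ND5	protein_coding	-	1719
trnH	trna	-	67
ND4	protein_coding	-	1338
ND4L	protein_coding	-	297
trnT	trna	+	66
trnP	trna	-	67
ND6	protein_coding	+	525
CYTB	protein_coding	+	1140
trnS2	trna	+	68
ND1	protein_coding	-	936
trnL1	trna	-	67
rrnL	rrna	-	1300
trnV	trna	-	70
rrnS	rrna	-	780
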