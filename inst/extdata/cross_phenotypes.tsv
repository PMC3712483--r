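# Six laboratory crosses: parental supergene diplotypes and F1 phenotype
# class counts (canonical class order; '-' = class not segregating).
cross_id	phase_label	father_id	father_h1	father_h2	mother_id	mother_h1	mother_h2	pink_unbanded	pink_banded	yellow_unbanded	yellow_banded	total
1	repulsion	C100	CP-Bb	Cy-BO	C101	Cy-Bb	Cy-Bb	0	56	47	0	103
2	repulsion	C108	CP-Bb	Cy-BO	C109	Cy-Bb	Cy-Bb	0	27	23	0	50
3	repulsion	C110	CP-Bb	Cy-BO	C111	Cy-Bb	Cy-Bb	0	17	10	0	27
4	repulsion	C112	CP-Bb	Cy-BO	C113	Cy-Bb	Cy-Bb	0	56	53	0	109
5	coupling	C114	CP-BO	Cy-Bb	C115	Cy-Bb	Cy-Bb	18	0	0	16	34
6	colour_only	C119	CP-Bb	Cy-Bb	C118	Cy-Bb	Cy-Bb	-	37	-	38	75
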