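# Genome-wide pooled codon usage of Beauveria bassiana (10,363 CDS;
# assembly ASM28067v1), transcribed from a published codon-usage survey of
# this fungus. `count` is the genome-wide total; `rscu_printed` is the RSCU
# value as printed alongside it (2 decimals).
amino_acid	codon	count	rscu_printed
Phe	UUU	97124	1.04
Phe	UUC	90092	0.96
Leu	UUA	15257	0.20
Leu	UUG	61046	0.80
Leu	CUU	69405	0.91
Leu	CUC	150168	1.96
Leu	CUA	36366	0.47
Leu	CUG	127510	1.66
Ile	AUU	100384	1.25
Ile	AUC	112518	1.41
Ile	AUA	27324	0.34
Met	AUG	115524	1.00
Val	GUU	63597	0.80
Val	GUC	143919	1.80
Val	GUA	28295	0.35
Val	GUG	83697	1.05
Tyr	UAU	44250	0.64
Tyr	UAC	93320	1.36
Cys	UGU	17074	0.51
Cys	UGC	49552	1.49
His	CAU	45803	0.73
His	CAC	80397	1.27
Gln	CAA	77403	0.73
Gln	CAG	133706	1.27
Asn	AAU	66104	0.73
Asn	AAC	115356	1.27
Lys	AAA	68568	0.57
Lys	AAG	173994	1.43
Asp	GAU	112138	0.74
Asp	GAC	192144	1.26
Glu	GAA	110930	0.73
Glu	GAG	193581	1.27
Ser	UCU	63684	0.92
Ser	UCC	81713	1.18
Ser	UCA	44120	0.64
Ser	UCG	84448	1.22
Ser	AGU	34859	0.50
Ser	AGC	106765	1.54
Pro	CCU	64901	0.86
Pro	CCC	98366	1.30
Pro	CCA	56636	0.75
Pro	CCG	82011	1.09
Thr	ACU	56368	0.74
Thr	ACC	99999	1.31
Thr	ACA	58385	0.77
Thr	ACG	89814	1.18
Ala	GCU	101796	0.82
Ala	GCC	202360	1.63
Ala	GCA	76891	0.62
Ala	GCG	116536	0.94
Trp	UGG	74428	1.00
Arg	CGU	44390	0.82
Arg	CGC	125865	2.33
Arg	CGA	47855	0.89
Arg	CGG	40937	0.76
Arg	AGA	36237	0.67
Arg	AGG	29101	0.54
Gly	GGU	72400	0.81
Gly	GGC	192920	2.16
Gly	GGA	52839	0.59
Gly	GGG	39116	0.44
Ter	UGA	3421	0.99
Ter	UAA	3595	1.04
Ter	UAG	3348	0.97
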