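# High- and low-bias pool codon counts of Beauveria bassiana, transcribed
# from the optimal-codon table of a published codon-usage survey (pools are
# the extremes of the gene set ranked by ENC). `*_printed` columns carry the
# RSCU values as printed. Two low-pool cells were garbled in the source
# ("0.9 7 4782" and "1.3 9 4816"); they are stored under the natural reading
# (0.97/4782, 1.39/4816) and flagged ambiguous=1 so fixture-based assertions
# can exclude them. `optimal_printed` marks the codons starred in the source.
amino_acid	codon	rscu_high_printed	n_high	rscu_low_printed	n_low	optimal_printed	ambiguous
Phe	UUU	0.99	3493	1.02	4006	0	0
Phe	UUC	1.01	3581	0.98	3865	0	0
Leu	UUA	0.02	52	0.52	1782	0	0
Leu	UUG	0.21	546	1.14	3947	0	0
Leu	CUU	0.37	956	1.25	4325	0	0
Leu	CUC	3.53	9236	1.14	3937	1	0
Leu	CUA	0.13	351	0.78	2684	0	0
Leu	CUG	1.74	4564	1.17	4053	1	0
Ile	AUU	1.09	3160	1.19	4431	0	0
Ile	AUC	1.85	5373	1.11	4157	1	0
Ile	AUA	0.05	159	0.70	2611	0	0
Met	AUG	1.00	3892	1.00	4860	0	0
Val	GUU	0.33	1072	1.11	3542	0	0
Val	GUC	2.83	9154	1.21	3887	1	0
Val	GUA	0.08	245	0.66	2128	0	0
Val	GUG	0.76	2474	1.02	3260	0	0
Tyr	UAU	0.20	531	1.02	2903	0	0
Tyr	UAC	1.80	4668	0.98	2809	1	0
His	CAU	0.22	434	1.09	3329	0	0
His	CAC	1.78	3436	0.91	2780	1	0
Gln	CAA	0.31	931	1.01	5088	0	0
Gln	CAG	1.69	4985	0.99	4946	1	0
Asn	AAU	0.27	815	1.04	4228	0	0
Asn	AAC	1.73	5282	0.96	3879	1	0
Lys	AAA	0.20	885	0.93	4872	0	0
Lys	AAG	1.80	8076	1.07	5585	1	0
Asp	GAU	0.29	1419	1.01	6628	0	0
Asp	GAC	1.71	8446	0.99	6509	1	0
Glu	GAA	0.33	1498	0.97	6665	0	0
Glu	GAG	1.67	7699	1.03	7095	1	0
Ser	UCU	0.47	971	1.16	3849	0	0
Ser	UCC	2.01	4120	0.83	2740	1	0
Ser	UCA	0.16	324	1.06	3500	0	0
Ser	UCG	1.52	3103	0.92	3056	1	0
Ser	AGU	0.12	243	0.78	2572	0	0
Ser	AGC	1.72	3523	1.26	4164	1	0
Pro	CCU	0.41	939	1.04	3239	0	0
Pro	CCC	2.41	5557	0.74	2302	1	0
Pro	CCA	0.15	337	1.32	4115	0	0
Pro	CCG	1.04	2409	0.90	2816	1	0
Thr	ACU	0.33	862	1.03	3441	0	0
Thr	ACC	2.22	5828	0.86	2873	1	0
Thr	ACA	0.21	549	1.23	4104	0	0
Thr	ACG	1.24	3259	0.88	2945	1	0
Ala	GCU	0.43	2078	1.07	5240	0	0
Ala	GCC	2.69	13066	0.97	4782	1	1
Ala	GCA	0.13	616	1.15	5659	0	0
Ala	GCG	0.76	3677	0.81	3992	0	0
Cys	UGU	0.13	135	0.86	1491	0	0
Cys	UGC	1.87	1916	1.14	1971	1	0
Trp	UGG	1.00	2681	1.00	3263	0	0
Arg	CGU	0.53	858	0.77	1920	0	0
Arg	CGC	4.50	7293	1.11	2778	1	0
Arg	CGA	0.18	288	1.35	3373	0	0
Arg	CGG	0.47	756	0.76	1916	0	0
Arg	AGA	0.13	215	1.21	3024	0	0
Arg	AGG	0.19	312	0.81	2022	0	0
Gly	GGU	0.47	1675	0.88	3074	0	0
Gly	GGC	3.22	11372	1.39	4816	1	1
Gly	GGA	0.14	486	1.06	3678	0	0
Gly	GGG	0.17	614	0.67	2332	0	0
Ter	UAA	1.73	299	1.01	175	0	0
Ter	UAG	0.76	132	1.01	175	0	0
Ter	UGA	0.50	87	0.97	168	0	0
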