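# Maruca vitrata mitochondrial codon usage (14 PCG coding sequences, RNA alphabet).
# count and rscu_printed are verbatim; the printed UCA count (12) is inconsistent
# with its own printed RSCU (2.06) and with the serine family's other RSCU values,
# all of which are consistent with a count of 75 -- count_corrected carries that
# reconstruction and equals the printed count everywhere else.
codon	aa	count	rscu_printed	count_corrected
UUU	F	315	1.82	315
UUC	F	31	0.18	31
UUA	L	426	5.26	426
UUG	L	9	0.11	9
CUU	L	26	0.32	26
CUC	L	2	0.02	2
CUA	L	23	0.28	23
CUG	L	0	0.00	0
AUU	I	394	1.91	394
AUC	I	18	0.09	18
AUA	M	240	1.85	240
AUG	M	19	0.15	19
GUU	V	71	2.07	71
GUC	V	4	0.12	4
GUA	V	59	1.72	59
GUG	V	3	0.09	3
UCU	S	98	2.69	98
UCC	S	8	0.22	8
UCA	S	12	2.06	75
UCG	S	1	0.05	1
CCU	P	74	2.47	74
CCC	P	8	0.27	8
CCA	P	38	1.27	38
CCG	P	0	0.00	0
ACU	T	83	2.35	83
ACC	T	8	0.23	8
ACA	T	49	1.39	49
ACG	T	1	0.03	1
GCU	A	75	2.52	75
GCC	A	9	0.30	9
GCA	A	35	1.18	35
GCG	A	0	0.00	0
UAU	Y	169	1.88	169
UAC	Y	11	0.12	11
UAA	*	10	1.82	10
UAG	*	1	0.18	1
CAU	H	60	1.82	60
CAC	H	6	0.18	6
CAA	Q	54	1.96	54
CAG	Q	1	0.04	1
AAU	N	202	1.87	202
AAC	N	14	0.13	14
AAA	K	73	1.70	73
AAG	K	13	0.30	13
GAU	D	55	1.75	55
GAC	D	8	0.25	8
GAA	E	68	1.89	68
GAG	E	4	0.11	4
UGU	C	28	1.87	28
UGC	C	2	0.13	2
UGA	W	88	1.96	88
UGG	W	2	0.04	2
CGU	R	12	0.94	12
CGC	R	0	0.00	0
CGA	R	37	2.90	37
CGG	R	2	0.16	2
AGU	S	31	0.85	31
AGC	S	1	0.03	1
AGA	S	76	2.09	76
AGG	S	0	0.00	0
GGU	G	57	1.19	57
GGC	G	0	0.00	0
GGA	G	117	2.45	117
GGG	G	17	0.36	17
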