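# Amino acid side-chain properties from Grantham (1974) Science 185:862-864.
# polarity is the AAIndex entry GRAR740102 (Polarity, Grantham 1974);
# composition is GRAR740101; volume is GRAR740103.
# Columns: one-letter code, three-letter code, composition c, polarity p, volume v.
aa	aa3	composition	polarity	volume
A	Ala	0.00	8.1	31
R	Arg	0.65	10.5	124
N	Asn	1.33	11.6	56
D	Asp	1.38	13.0	54
C	Cys	2.75	5.5	55
Q	Gln	0.89	10.5	85
E	Glu	0.92	12.3	83
G	Gly	0.74	9.0	3
H	His	0.58	10.4	96
I	Ile	0.00	5.2	111
L	Leu	0.00	4.9	111
K	Lys	0.33	11.3	119
M	Met	0.00	5.7	105
F	Phe	0.00	5.2	132
P	Pro	0.39	8.0	32.5
S	Ser	1.42	9.2	32
T	Thr	0.71	8.6	61
W	Trp	0.13	5.4	170
Y	Tyr	0.20	6.2	136
V	Val	0.00	5.9	84
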