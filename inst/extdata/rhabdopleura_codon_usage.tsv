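# Codon usage of the 13 mitochondrial protein-coding genes of
# Rhabdopleura compacta (published counts; amino acids follow the
# Rhabdopleura mitochondrial code: AUA=Ile, AAA=Lys, AGA=Ser, AGG=Lys).
codon	count	aa
UUU	554	Phe
UUC	35	Phe
UUA	205	Leu
UUG	210	Leu
UCU	233	Ser
UCC	8	Ser
UCA	32	Ser
UCG	21	Ser
UAU	159	Tyr
UAC	28	Tyr
UAA	2	term
UAG	9	term
UGU	99	Cys
UGC	10	Cys
UGA	48	Trp
UGG	89	Trp
CUU	102	Leu
CUC	5	Leu
CUA	19	Leu
CUG	14	Leu
CCU	93	Pro
CCC	5	Pro
CCA	10	Pro
CCG	11	Pro
CAU	70	His
CAC	8	His
CAA	16	Gln
CAG	31	Gln
CGU	46	Arg
CGC	4	Arg
CGA	15	Arg
CGG	19	Arg
AUU	175	Ile
AUC	9	Ile
AUA	52	Ile
AUG	96	Met
ACU	76	Thr
ACC	3	Thr
ACA	5	Thr
ACG	5	Thr
AAU	79	Asn
AAC	8	Asn
AAA	10	Lys
AAG	59	Lys
AGU	87	Ser
AGC	10	Ser
AGA	40	Ser
AGG	20	Lys
GUU	289	Val
GUC	17	Val
GUA	39	Val
GUG	64	Val
GCU	99	Ala
GCC	4	Ala
GCA	12	Ala
GCG	11	Ala
GAU	60	Asp
GAC	9	Asp
GAA	17	Glu
GAG	59	Glu
GGU	158	Gly
GGC	8	Gly
GGA	63	Gly
GGG	182	Gly
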