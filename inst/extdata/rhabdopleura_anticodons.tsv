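# The 22 tRNA anticodons (5'->3') of the Rhabdopleura compacta
# mitogenome, as marked in the published codon-usage and genetic-code
# tables (the marked codon of each family is the reverse complement of
# its tRNA's anticodon; tRNA-Lys carries CUU rather than UUU).
name	aa	anticodon
trnF	Phe	GAA
trnL1	Leu	UAA
trnL2	Leu	UAG
trnS1	Ser	UGA
trnS2	Ser	GCU
trnY	Tyr	GUA
trnC	Cys	GCA
trnW	Trp	UCA
trnP	Pro	UGG
trnH	His	GUG
trnQ	Gln	UUG
trnR	Arg	UCG
trnI	Ile	GAU
trnM	Met	CAU
trnT	Thr	UGU
trnN	Asn	GUU
trnK	Lys	CUU
trnV	Val	UAC
trnA	Ala	UGC
trnD	Asp	GUC
trnE	Glu	UUC
trnG	Gly	UCC
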