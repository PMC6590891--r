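# Primers of the jellyfish SLC6 cloning / antisense RT-PCR design, as printed.
# Note: the source prints the same phage-arm sequence twice for what its text
# calls two arm primers (PA143/PA144); it is shipped once under PA144.
# TR-1/TR-2 roles are nominal (the source pairs each with a phage-arm primer).
name	seq	role
iNAT6R	GCACAACCGGTCCACTCCRTANANCCA	reverse
PA144	GTATCGGCGGAATTCGTCGA	forward
TR-1	CTGATTGCCTTGTTCCAGGT	forward
TR-2	GGGCTGGGTGGATTTCCTTC	reverse
nuc52_76	ATTGCCAAGACGGAGTCCATCAAGG	forward
For_176	TTTGTCAGAAGAATGGAGGAGGTGC	forward
Rev_757	CCTTTCCGCTGGACTGGATACCTT	reverse
For_293	CCCTCTTGGCATGGAAGGAAA	forward
Rev_684	GAGTTTGGCATTGAGGCCGA	reverse
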