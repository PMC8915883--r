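count	freq	cdr3nt	cdr3aa	v	d	j
12	0.3	TGTGCCAGCAGTCTGAACGAGCAGTTC	CASSLNEQF	TRBV2	.	TRBJ2-1
9	0.225	TGTGCCAGCAGCAAGACCGAGGCCTTC	CASSKTEAF	TRBV4-1	.	TRBJ1-1
7	0.175	TGCAGTGCCTGGACCCAGTACTTC	CSAWTQYF	TRBV20-1*01	.	TRBJ2-3
5	0.125	TGTGCCACCAGCGGCGAGCTGTTT	CATSGELF	TRBV28	.	TRBJ2-2
4	0.1	TGTGCCAGCAGTTAAGAGCAGTTC	CASS*EQF	TRBV2	.	TRBJ2-1
3	0.075	TGTGCCAGCTCCTACACCTT	CASSYT_	TRBV27	.	TRBJ1-2
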