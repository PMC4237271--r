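gene	direction	sequence
AP2	F	TGGTTGATTTTCCATCCCAT
AP2	R	GCCAGGAATTTGACGAAGTC
PPARG	F	GCTTCTGGATTTCACTATGG
PPARG	R	AAACCTGATGGCATTATGAG
ADIPOQ	F	GCAGTCTGTGGTTCTGATTCCATAC
ADIPOQ	R	GCCCTTGAGTCGTGGTTTCC
LEP	F	CAGCGGTTGCAAGGCCCAAGA
LEP	R	GGCCAAAGCCACAAGAATCCGC
GAPDH	F	CTGGTAAAGTGGATATTGTTGCCAT
GAPDH	R	TGGAATCATATTGGAACATGTAAACC
ALPL	F	GACGGACCCTCGCCAGTGCT
ALPL	R	AATCGACGTGGGTGGGAGGGG
OSTEONECTIN	F	GAGGAAACCGAAGAGGAGG
OSTEONECTIN	R	GGGGTGTTGTTCTCATCCAG
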