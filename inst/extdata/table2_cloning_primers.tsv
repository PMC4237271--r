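name	direction	sequence
RUNX2_wt_UTR	F	GTTGTTACTAGTTCTTTGAATGCCTCTAACACAGCTTTGCCTTTACCCAAGGCCCCACTGGCAGCTTTCCACATATCAGAGTTCCAGA
RUNX2_wt_UTR	R	GTTGTTAAGCTTTCCTTAAAGCTGTACACACATCTCCTCAAACCAAAGCTGTGGTACCTGTTCTGGAACTCTGATATGTGGAAAGCTG
RUNX2_mut_UTR	F	GTTGTTACTAGTTCTTTGAATGCCTCTAACAagaagggGCCTTTACCCAAGGCCCCACTGGagaagggCCACATATCAGAGTTCCAGA
RUNX2_mut_UTR	R	GTTGTTAAGCTTTCCTTcccttctTACACACATCTCCTCAAACCcccttctTGGTACCTGTTCTGGAACTCTGATATGTGGcccttct
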