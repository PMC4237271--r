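>hsa-miR-320c mature miRNA, miRBase MIMAT0005793
AAAAGCUGGGUUGAGAGGGU
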