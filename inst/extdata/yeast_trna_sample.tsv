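# Sample tRNA isoacceptor table in Genomic tRNA Database export style:
# the two cytosolic alanine isoacceptors of Saccharomyces cerevisiae
# with their genomic gene copy numbers.
amino_acid	anticodon	copies
Ala	AGC	11
Ala	UGC	5
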