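# Alanine codon usage in the Saccharomyces cerevisiae genome.
# GCU and GCC are published genome-wide counts; the GCA/GCG rows are a
# SYNTHETIC split of their published combined total of 66324, apportioned
# by typical relative usage of the two codons in yeast.
family	codon	count
A	GCU	58952
A	GCC	35580
A	GCA	48200
A	GCG	18124
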