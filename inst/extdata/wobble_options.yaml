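# Wobble-option sets: for each anticodon wobble base, the alternative
# sets of codon third-position bases a tRNA may read. C and G are fixed
# by nucleotide chemistry (C:G cognate only; G reads both pyrimidines);
# A (often modified to inosine) and U (subject to several chemical
# modifications) admit multiple experimentally observed readings.
# Every option set contains the Watson-Crick partner of the wobble base.
A:
  - [U]
  - [U, C]
  - [U, C, A]
U:
  - [A]
  - [A, G]
  - [A, G, U]
  - [A, C, G]
  - [A, C, G, U]
C:
  - [G]
G:
  - [C, U]
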