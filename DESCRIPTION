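Package: wobblescan
Title: Inferring tRNA Anticodon-Codon Reading from Codon Usage Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the imprint of tRNA decoding on codon usage bias and
    predicts the binary anticodon-codon reading assignment of each
    amino-acid family from coding sequences and tRNA gene copy numbers.
    Implements three sequence-based scoring methods (a hidden Markov model
    over hidden tRNA states, a through-origin quadratic regression of tRNA
    abundance on summed codon counts, and a consecutive-synonymous-codon
    correlation score), enumeration of binary reading hypotheses with a
    configurable plausibility restriction, Crick wobble-rule and
    wobble-parsimony baselines, randomization-based empirical p-values,
    cross-method consensus tallies, and a synthetic-corpus simulator with
    known ground-truth readings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
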