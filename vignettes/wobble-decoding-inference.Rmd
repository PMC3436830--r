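---
title: "Inferring tRNA codon reading from codon usage bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tRNA codon reading from codon usage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wobblescan)
```

## The inference problem

Each amino acid is decoded by one or more tRNA isoacceptors whose
anticodons pair antiparallel with the mRNA codon. Positions 1–2 of the
codon demand strict Watson–Crick pairing; position 3 (the wobble
position, paired with the first anticodon base) tolerates non-canonical
pairings, especially when the wobble base is chemically modified. The
object of inference is the *reading matrix* of a family: a binary
tRNA × codon matrix with a 1 wherever the tRNA can decode the codon. A
valid matrix leaves no codon unreadable and no tRNA idle. `wobblescan`
scores reading hypotheses against genomic evidence; it does not model
*relative* reading efficiencies — the interaction is binary by
assumption, and cross-box reading (a tRNA decoding codons of another
amino acid) is excluded.

Three simplifications keep the space tractable. First, six-codon
families (Ser, Leu, Arg) are split into their standard-code boxes
(codons sharing positions 1–2) and analyzed per box, since decoding does
not cross boxes. Second, the full space of valid binary matrices —
enumerated by `enumerate_all_readings()` and used as the reference
distribution for score normalization — is contrasted with the much
smaller *plausible* subset: the cross-product over tRNAs of
experimentally observed wobble options. Third, the wobble options are
configuration, not code (`inst/extdata/wobble_options.yaml`): C-wobble
tRNAs read only the G-ending codon and G-wobble tRNAs both pyrimidine
codons (these two are enforced), while A- and U-wobble tRNAs admit
several option sets reflecting inosine and uridine modifications:

```
A: {U}, {U,C}, {U,C,A}
U: {A}, {A,G}, {A,G,U}, {A,C,G}, {A,C,G,U}
```

This set was reconstructed from the readings observed across published
decoding experiments (IUPAC classes A, R, D, N, V, Y at the wobble
position); because the published figure of plausible mappings is not
machine-readable, users can override the file. Every option contains
the Watson–Crick partner of the wobble base, which the loader enforces.
A combination whose union fails to cover the family's codons is dropped
during enumeration of plausible readings. We do not additionally require
each tRNA to read its cognate codon — coverage is the only constraint —
since the evidence for readings that skip the cognate is equivocal; the
option sets above all contain the cognate anyway.

Modified wobble bases (inosine, mcm5U, ncm5U, ...) are handled as their
unmodified parent nucleotide for all sequence purposes; modification
identity is never inferred from sequence.

## The three scores

**HMM.** For one family, hidden states are the tRNAs and the observable
is the ordered run of the family's codons within a gene (spacing
ignored; runs never cross genes). The model λ = {E, T, π} is fully
determined by the hypothesis:

- `E[i, j] = 1/k_i` over the `k_i` codons tRNA *i* reads, else 0 —
  uniform because the interaction is binary.
- `T[i, j] ∝ w_j` off the diagonal, with `w_j` the relative gene copy
  number (the abundance proxy), and `T[i, i] ∝ w_i + max(0, α + β w_i)`
  before row renormalization. The additive clamped form was chosen from
  the looser statement "a linear term added to the diagonal" because,
  with β < 0, it boosts the reuse of *rare* tRNAs, which is the observed
  direction. The covariate is relative frequency, not absolute copies
  (configurable in spirit: pass your own `reuse_params`); the estimate
  is global across families by default, per-family if called per family.
- π is the stationary left eigenvector of T (translation is an ongoing
  process, so limiting usage is the natural start); with the abundance
  vector as a documented fallback when the eigen route fails. The choice
  has little effect in practice.

`T` and π are shared by all hypotheses of a family; only `E` differs, so
likelihood differences reflect the reading alone. Scoring sums the
scaled forward log-likelihood over runs (stable for runs up to 1e5); no
parameter is optimized during evaluation.

The reuse parameters (defaults α = 0.065, β = −0.087, the values
pre-estimated from yeast) can be re-estimated with `estimate_reuse()`:
iterate {build T → Viterbi-decode runs under a fixed reference reading →
convert each state's self-transition frequency `f_i` to an implied
diagonal excess `d_i = (f_i − w_i)/(1 − f_i)` → weighted least squares
of `d_i` on `w_i`}. The reference reading during estimation is the
restricted wobble-rules reading — it is hypothesis-neutral and, for the
common A/U isoacceptor pairs, emission-disjoint, which makes the state
decoding exact. Viterbi ties break toward the lower state index.
Convergence is declared when both parameter changes fall below `tol`
(so `tol = Inf` returns the initial values after one diagnostic pass);
non-convergence after `max_iter` is flagged, not an error.

**REG.** Abundant tRNAs pair with frequent codons, empirically as
tRNA ≈ γx² (the quadratic law; linear and logarithmic alternatives fit
known readings worse and are out of scope). `x_i` sums the family's
codon counts over the codons tRNA *i* reads, with shared codons split by
the sharing weights `n_{c,i} = (1/k_i)/Σ_{j reads c}(1/k_j)` so that
`Σ_i x_i` always equals the family total. The one-parameter
through-origin fit has the closed form `γ̂ = Σx²y/Σx⁴`; fit quality is
the *uncentered* R² = 1 − Σε²/Σy², because the centered variant is
ill-defined without an intercept and can mislead (it remains available
behind `centered = TRUE`). tRNAs with zero gene copies are excluded —
their abundance proxy is undefined; a family left with fewer than two
tRNAs is flagged trivial rather than scored. Raw counts are used rather
than frequencies; the ranking is scale-invariant either way.

**CC.** Consecutive synonymous codons correlate positively, and codons
decoded by the same tRNA correlate as blocks. `X[i, j]` counts
occurrences of codon *i* followed by codon *j* at the next instance of
the amino acid in the same gene. Under independence each cell is
binomial: `E = N p_i p_j`, `V = N p_i p_j (1 − p_i p_j)`, with `p` the
corpus-wide within-family frequencies (per-gene frequencies would absorb
expression-level structure; the global expectation is the deliberate
choice). A hypothesis contributes `C[i, j] = +1` when codons *i* and *j*
share at least one tRNA (so ties in block membership favor broader
readings), −1 otherwise; the diagonal — generic same-codon reuse bias —
is excluded. The score is `z_total = (Σ C·X − Σ C·E)/sqrt(Σ V)` over
off-diagonal cells. The denominator treats cells as independent, which
is an approximation consistent with the binomial model; it is used for
ranking and randomization, never as a nominal normal p-value. Two known
blind spots are flagged rather than scored: a family where one tRNA
reads everything (C is all +1, no contrast) and two-codon families with
a single tRNA.

## Filters and counting conventions

CDS records are rejected with reason codes checked in a fixed order:
`non_triplet` (the observable proxy for programmed frameshifts in plain
FASTA), `ambiguous` (any character outside A/C/G/U/T), `internal_stop`,
and `short` (fewer than 50 amino acids after stripping the terminal stop
codon, which is never counted). Input is case-insensitive and accepts
DNA or RNA; everything is U internally. The ≥3-instances rule — a gene
contributes a family's run only with at least three occurrences of the
amino acid — applies to the runs consumed by HMM and CC; the plain codon
totals for REG use all retained genes, which is the reading of the
filter that keeps REG's frequencies unbiased. Pairs never cross gene
boundaries.

## Significance and consensus

Scores across a solution space are min–max normalized,
`s_n = (s − min s)/(max s − min s)`, mapping the space onto
[0, 1]; all-equal scores yield 0.5 with a degeneracy flag. The null for
HMM and CC redraws each run's codons i.i.d. from the family frequencies
(run lengths and gene structure preserved); the null for REG draws each
codon count from a skew-normal moment-matched (mean, variance, skewness;
skewness clamped to the admissible |γ₁| < 0.995, shape 0 below three
codons, negative draws clamped to 0) to the family's count distribution.
The empirical p-value of the real best-plausible score against n = 99
replicate best-plausible scores is `p = (r + 1)/(n + 1)` with ties
counted in r — so beating all replicates gives 0.01 and ranking second
0.02, and under an exchangeable null p is uniform on its support. The
formula is the standard Monte-Carlo estimator; it is pinned by the
rank-1/rank-2 values above. Cross-method agreement is exact reading-
matrix equality; `consensus_tally()` partitions families into five
regions (all three agree, one of three pairs agrees, none agree) and
estimates expected counts and per-region Monte-Carlo p-values from
randomized replicates, the simulated route being the one we can make
reproducible.

## The simulator, and what passing tests show

`simulate_corpus()` is the generative mirror of the scoring HMM: amino
acids i.i.d. from a configured composition, then per family the hidden
tRNA chain run forward with codons emitted uniformly over the
ground-truth reading (optionally skewed via `emission_skew`);
`simulate_null_corpus()` emits i.i.d. codons from the stationary mix
instead. Genes carry a terminal stop and are written as DNA to exercise
the transliteration path. Defaults mirror the study conditions: reuse
(0.065, −0.087), genes of mean length 150 amino acids (Poisson,
truncated at 50 so everything clears the default filters).

The recovery suite uses corpora of four two-isoacceptor four-codon
families (gene copy numbers (11,5), (9,8), (13,7), (10,4) — an A- and a
U-wobble tRNA each, the commonest non-trivial configuration), 1000
genes for reading recovery over 20 seeds, and 2000 genes of mean length
240 for reuse-parameter recovery — sizes at which the estimator's
sampling error is comfortably inside the ±0.02 acceptance band, as
pilot precision analysis predicted. On these corpora the HMM and CC
rank the true reading first in 20/20 replicates, and the inferred
reading is unchanged under ±10% multiplicative noise on the transition
probabilities (the model is dominated by its emissions). REG recovers
the truth in 0/20 — a real and instructive mismatch, not a bug: the
generative chain produces codon usage *linear* in tRNA abundance,
whereas REG assumes the quadratic law, so its preferred readings
flatten the abundance ratio. REG's recovery under data generated from
its own law is exact (see `test-regression.R`), and on the real yeast
alanine counts REG ranks the experimentally established reading first.

What the simulator does not emulate: expression-level heterogeneity and
its codon-bias gradient, GC-content variation along the genome, amino-
acid autocorrelation in real proteins, and tRNA abundance fluctuating
with growth condition. Passing recovery tests therefore demonstrates
correctness of the inference machinery under the model's own
assumptions, not that real genomes satisfy those assumptions; on real
data the three methods are designed to disagree informatively, which is
what the consensus tally measures.

## Numerical choices and limitations

Forward and Viterbi recursions run scaled/in log space and are
vectorized across runs; forward equals exhaustive path enumeration to
1e-12 relative tolerance on small models. Canonical codon order
(U < C < A < G per position) fixes all matrix layouts; reading
identifiers are row-wise bit strings like `1100|0011`. Full enumeration
is guarded (default 2^21 candidate matrices) — highly degenerate
families would otherwise explode combinatorially, and the pipeline then
normalizes over the plausible subset only, recording the fact. Stop
codons, tRNA gene finding, modification prediction, expression
stratification, and adaptation indices such as tAI are out of scope.
Wobble parsimony is refused in prokaryote mode: its premise (canonical
decoding wherever a cognate tRNA exists) does not hold for bacteria,
whose tRNAs typically read more broadly.
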