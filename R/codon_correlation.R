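# Codon-correlation (CC) method: block structure in the z-transformed
# matrix of consecutive synonymous codon pairs.

#' Expected pair counts and variances under independence
#'
#' Treating consecutive codon occurrences as independent draws from the
#' family's overall codon frequencies, each cell of the pair matrix is
#' binomial with `N_pairs` trials and success probability `p_i * p_j`:
#' `E[i,j] = N p_i p_j`, `V[i,j] = N p_i p_j (1 - p_i p_j)`.
#'
#' @param counts codon counts covering the family (a `codon_counts` or
#'   named vector).
#' @param pairs a `pair_counts`.
#' @return list with matrices `E` and `V` (codon dimnames).
#' @export
expected_pairs <- function(counts, pairs) {
  stopifnot(inherits(pairs, "pair_counts"))
  cnt <- family_counts(counts, pairs$family)
  if (sum(cnt) <= 0) {
    stop("no codon counts for family", call. = FALSE)
  }
  p <- cnt / sum(cnt)
  N <- pairs$n_pairs
  P <- outer(p, p)
  E <- N * P
  V <- N * P * (1 - P)
  list(E = E, V = V)
}

#' Z-transformed pair-count matrix
#'
#' Cellwise standardization `Z = (X - E) / sqrt(V)`; cells with zero
#' variance are set to 0 and recorded in the `mask` attribute.
#'
#' @param pairs a `pair_counts`.
#' @param E,V expectation and variance matrices (from
#'   [expected_pairs()]); computed from `counts` when omitted.
#' @param counts codon counts, used when `E`/`V` are missing.
#' @return an object of class `z_matrix`: list with `family`, `Z`, `E`,
#'   `V`, `X`.
#' @export
z_matrix <- function(pairs, E = NULL, V = NULL, counts = NULL) {
  stopifnot(inherits(pairs, "pair_counts"))
  if (is.null(E) || is.null(V)) {
    if (is.null(counts)) {
      stop("supply either E and V or codon counts", call. = FALSE)
    }
    ev <- expected_pairs(counts, pairs)
    E <- ev$E; V <- ev$V
  }
  stopifnot(identical(dim(E), dim(pairs$X)), identical(dim(V), dim(pairs$X)))
  Z <- matrix(0, nrow(E), ncol(E), dimnames = dimnames(pairs$X))
  ok <- V > 0
  Z[ok] <- (pairs$X[ok] - E[ok]) / sqrt(V[ok])
  structure(list(family = pairs$family, Z = Z, E = E, V = V, X = pairs$X,
                 mask = ok),
            class = "z_matrix")
}

#' @export
print.z_matrix <- function(x, ...) {
  cat(sprintf("Z matrix for %s:\n", x$family$amino_acid))
  print(round(x$Z, 1))
  invisible(x)
}

#' Codon-correlation block score of a reading hypothesis
#'
#' The sign matrix `C` has +1 where the two codons are read by at least
#' one common tRNA under the candidate reading and -1 otherwise. Over
#' the off-diagonal cells (the diagonal, which carries the generic
#' same-codon reuse bias, is ignored) the observed signed sum
#' `s_obs = sum C X` is compared with its expectation under
#' independence, standardized by the total standard deviation
#' `sqrt(sum V)`: the reading with the highest `z_total` is the CC
#' prediction. A 2-codon family with a single tRNA carries no contrast
#' and is flagged trivial. The hypothetical reading in which every tRNA
#' reads every codon makes `C` all +1 and is flagged degenerate.
#'
#' @param reading a `reading_matrix`.
#' @param pairs a `pair_counts`.
#' @param counts codon counts (for the expectation); or pass a
#'   precomputed `zmat`.
#' @param zmat optional precomputed `z_matrix` (saves recomputation when
#'   scoring many readings).
#' @return an object of class `cc_score`: list with `reading`, `C`,
#'   `s_obs`, `s_exp`, `z_total`, `trivial`, `degenerate`.
#' @export
score_reading_cc <- function(reading, pairs, counts = NULL, zmat = NULL) {
  if (is.null(zmat)) zmat <- z_matrix(pairs, counts = counts)
  reads <- reading$reads
  # shared[i, j] = 1 iff some tRNA reads both codon i and codon j
  shared <- (t(reads) %*% reads) > 0
  C <- ifelse(shared, 1, -1)
  off <- row(C) != col(C)
  s_obs <- sum(C[off] * zmat$X[off])
  s_exp <- sum(C[off] * zmat$E[off])
  v_tot <- sum(zmat$V[off])
  z_total <- if (v_tot > 0) (s_obs - s_exp) / sqrt(v_tot) else NA_real_
  trivial <- nrow(reads) < 2L && ncol(reads) <= 2L
  structure(list(reading = reading, C = C, s_obs = s_obs, s_exp = s_exp,
                 z_total = z_total, trivial = trivial,
                 degenerate = all(C[off] == 1)),
            class = "cc_score")
}

#' @export
print.cc_score <- function(x, ...) {
  cat(sprintf("CC score %s: z_total = %.4f (s_obs = %.1f, s_exp = %.1f)\n",
              reading_id(x$reading), x$z_total, x$s_obs, x$s_exp))
  invisible(x)
}

#' Export a Z matrix as TSV
#'
#' Writes the z-transformed pair matrix with codon row and column
#' labels.
#'
#' @param zmat a `z_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_z_matrix <- function(zmat, path) {
  df <- data.frame(codon = rownames(zmat$Z), zmat$Z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
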