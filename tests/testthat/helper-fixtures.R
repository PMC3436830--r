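# Shared fixtures and independent oracles for the test suite.

std_code <- genetic_code(1)
ala_family <- family_of(std_code, "Ala")
ala_trnas <- trna_set(c("Ala", "Ala"), c("AGC", "UGC"), c(11, 5))

# the experimentally known yeast alanine reading: AGC -> {GCU, GCC},
# UGC -> {GCA, GCG}
ala_true_reading <- reading_matrix(ala_family, ala_trnas,
                                   rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))

toy_family <- function(k, prefix = "GC") {
  structure(list(amino_acid = "A",
                 codons = paste0(prefix, c("U", "C", "A", "G")[seq_len(k)])),
            class = "aa_family")
}

toy_trnas <- function(n, copies = rep(1, n)) {
  # distinct anticodons with assorted wobble bases
  wb <- c("A", "U", "C", "G")[seq_len(n)]
  trna_set(rep("Ala", n), paste0(wb, "GC"), copies)
}

# Brute-force enumeration oracle: all binary n x k matrices with full
# row and column coverage, as a set of reading-id strings.
enumerate_oracle_ids <- function(n, k) {
  total <- 2^(n * k)
  ids <- character(0)
  for (mask in 0:(total - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n * k)]
    m <- matrix(bits, n, k, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      ids <- c(ids, paste(apply(m, 1, paste, collapse = ""), collapse = "|"))
    }
  }
  ids
}

# Path-enumeration oracle for the HMM forward probability.
forward_oracle <- function(E, T, pi, idx) {
  E <- unname(E); T <- unname(T); pi <- unname(pi)
  S <- nrow(E)
  L <- length(idx)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), L)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    pr <- pi[p[1]] * E[p[1], idx[1]]
    if (L >= 2) {
      for (t in 2:L) pr <- pr * T[p[t - 1], p[t]] * E[p[t], idx[t]]
    }
    total <- total + pr
  }
  log(total)
}

# random valid reading matrix (row+column coverage) for property tests
random_reading <- function(family, trnas, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trnas)
  k <- length(family$codons)
  repeat {
    m <- matrix(rbinom(n * k, 1, 0.5), n, k)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      return(reading_matrix(family, trnas, m))
    }
  }
}

make_sim <- function(n_genes = 200, seed = 1, reuse = reuse_params(),
                     readings = list(A = ala_true_reading),
                     mean_length_aa = 120, ...) {
  sim_config(readings, reuse = reuse, n_genes = n_genes,
             mean_length_aa = mean_length_aa, seed = seed, ...)
}

write_fasta_tmp <- function(seqs, names = NULL) {
  path <- tempfile(fileext = ".fasta")
  if (is.null(names)) names <- paste0("g", seq_along(seqs))
  writeLines(paste0(">", names, "\n", seqs), path)
  path
}
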