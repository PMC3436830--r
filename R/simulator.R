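# Synthetic CDS corpora with known ground-truth reading: the generative
# mirror of the scoring HMM. Genes are i.i.d. amino-acid sequences; per
# family the tRNA Markov chain (abundance-based transitions plus reuse
# boost) is run forward and codons are emitted uniformly over the
# reading of the hidden tRNA.

#' Simulation configuration
#'
#' @param readings named list of `reading_matrix` objects, one per
#'   amino-acid family (codon box): the ground truth to be recovered.
#'   Each carries its own tRNA set with gene copy numbers.
#' @param reuse a `reuse_params` driving the hidden-chain diagonal
#'   (default: the yeast-estimated values).
#' @param n_genes number of genes.
#' @param mean_length_aa mean gene length in amino acids (Poisson,
#'   truncated below at `min_length_aa`).
#' @param min_length_aa minimum gene length (default 50, clearing the
#'   default filter policy).
#' @param composition named numeric vector of amino-acid proportions
#'   over the configured families (default uniform); must sum to 1.
#' @param emission_skew optional named list (by family) of non-negative
#'   weight matrices with the dimensions of the family's reading matrix:
#'   relative codon preferences of each tRNA within the codons it reads.
#'   Default `NULL` = uniform emission over read codons, matching the
#'   binary-interaction assumption.
#' @param code a `genetic_code`.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(readings, reuse = reuse_params(), n_genes = 1000L,
                       mean_length_aa = 150, min_length_aa = 50L,
                       composition = NULL, emission_skew = NULL,
                       code = genetic_code(1), seed = 1L) {
  stopifnot(length(readings) >= 1L,
            all(vapply(readings, inherits, logical(1), "reading_matrix")))
  if (is.null(names(readings)) || any(names(readings) == "")) {
    names(readings) <- vapply(readings, function(r) r$family$amino_acid, character(1))
  }
  for (r in readings) {
    if (sum(r$trnas$copies) <= 0) {
      stop(sprintf("family %s has no tRNA gene copies", r$family$amino_acid),
           call. = FALSE)
    }
    if (any(colSums(r$reads) == 0L)) {
      stop(sprintf("family %s: ground-truth reading leaves codons uncovered",
                   r$family$amino_acid), call. = FALSE)
    }
  }
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / length(readings), length(readings)),
                                   names(readings))
  }
  stopifnot(length(composition) == length(readings),
            abs(sum(composition) - 1) < 1e-8, all(composition > 0))
  names(composition) <- names(readings)
  if (mean_length_aa < min_length_aa) {
    stop("mean gene length below the minimum length", call. = FALSE)
  }
  if (!is.null(emission_skew)) {
    for (f in names(emission_skew)) {
      sk <- emission_skew[[f]]
      r <- readings[[f]]
      stopifnot(!is.null(r), identical(dim(sk), dim(r$reads)), all(sk >= 0))
      if (any(rowSums(sk * r$reads) == 0)) {
        stop(sprintf("family %s: emission skew zeroes out a tRNA", f),
             call. = FALSE)
      }
    }
  }
  structure(list(readings = readings, reuse = reuse,
                 emission_skew = emission_skew,
                 n_genes = as.integer(n_genes),
                 mean_length_aa = mean_length_aa,
                 min_length_aa = as.integer(min_length_aa),
                 composition = composition, code = code,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# vectorized forward sampling of the hidden chain + emissions for a set
# of runs with given lengths; returns a list of codon-index vectors
.sample_chain_codons <- function(E, T, pi, lens) {
  n <- length(lens)
  if (n == 0L) return(list())
  maxlen <- max(lens)
  S <- nrow(E)
  k <- ncol(E)
  cumT <- t(apply(T, 1, cumsum))
  cumE <- t(apply(E, 1, cumsum))
  cumT[, S] <- 1; cumE[, k] <- 1
  states <- matrix(1L, n, maxlen)
  codons <- matrix(1L, n, maxlen)
  states[, 1L] <- findInterval(stats::runif(n), cumsum(pi),
                               rightmost.closed = FALSE) + 1L
  states[, 1L] <- pmin(states[, 1L], S)
  codons[, 1L] <- .sample_emission(cumE, states[, 1L], k)
  if (maxlen >= 2L) {
    for (t in 2:maxlen) {
      prev <- states[, t - 1L]
      u <- stats::runif(n)
      states[, t] <- rowSums(matrix(u, n, S) > cumT[prev, , drop = FALSE]) + 1L
      codons[, t] <- .sample_emission(cumE, states[, t], k)
    }
  }
  lapply(seq_len(n), function(i) codons[i, seq_len(lens[i])])
}

.sample_emission <- function(cumE, states, k) {
  n <- length(states)
  u <- stats::runif(n)
  rowSums(matrix(u, n, k) > cumE[states, , drop = FALSE]) + 1L
}

.sample_iid_codons <- function(p, lens) {
  draws <- sample.int(length(p), sum(lens), replace = TRUE, prob = p)
  split(draws, rep(seq_along(lens), lens))
}

.assemble_corpus <- function(config, iid = FALSE) {
  set.seed(config$seed)
  n <- config$n_genes
  keys <- names(config$readings)
  if (n == 0L) {
    return(list(sequences = character(0), names = character(0)))
  }
  lens <- pmax(config$min_length_aa,
               stats::rpois(n, config$mean_length_aa))
  gene_id <- rep(seq_len(n), lens)
  key_seq <- sample(keys, sum(lens), replace = TRUE,
                    prob = config$composition)
  codon_seq <- character(length(key_seq))
  for (f in keys) {
    reading <- config$readings[[f]]
    sel <- key_seq == f
    m_g <- tabulate(gene_id[sel], nbins = n)
    nz <- which(m_g > 0L)
    if (length(nz) == 0L) next
    E <- build_emissions(reading)
    if (!is.null(config$emission_skew[[f]])) {
      E <- reading$reads * config$emission_skew[[f]]
      E <- E / rowSums(E)
    }
    T <- build_transitions(reading$trnas, config$reuse)
    pi <- stationary_start(T)
    runs <- if (iid) {
      .sample_iid_codons(drop(pi %*% E), m_g[nz])
    } else {
      .sample_chain_codons(E, T, pi, m_g[nz])
    }
    codon_seq[sel] <- reading$family$codons[unlist(runs)]
  }
  seqs <- vapply(split(codon_seq, gene_id), paste, character(1), collapse = "")
  # terminal stop codon, then DNA for FASTA realism
  seqs <- chartr("U", "T", paste0(seqs, config$code$stop_codons[1]))
  list(sequences = unname(seqs), names = sprintf("sim_gene_%05d", seq_len(n)))
}

.sim_truth <- function(config) {
  list(
    seed = config$seed,
    reuse = list(alpha = config$reuse$alpha, beta = config$reuse$beta),
    n_genes = config$n_genes,
    mean_length_aa = config$mean_length_aa,
    composition = as.list(config$composition),
    families = lapply(config$readings, function(r) {
      list(amino_acid = r$family$amino_acid,
           codons = r$family$codons,
           anticodons = r$trnas$anticodon,
           copies = r$trnas$copies,
           reading = unname(apply(r$reads, 1, paste, collapse = "")),
           reading_id = reading_id(r))
    })
  )
}

#' Simulate a CDS corpus with known ground-truth reading
#'
#' Runs the generative HMM forward for every configured family and
#' interleaves the emitted codons in gene order. Output genes carry a
#' terminal stop codon and are written as DNA (T) to exercise the
#' transliteration path of the loader.
#'
#' @param config a `sim_config`.
#' @param fasta_path optional path; when given, the corpus is written as
#'   FASTA.
#' @param truth_path optional path; when given, the ground truth (seed,
#'   parameters, reading matrices) is written as JSON.
#' @return an object of class `sim_corpus`: list with `sequences` (DNA
#'   strings), `names`, `truth`, and `config`.
#' @export
simulate_corpus <- function(config, fasta_path = NULL, truth_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- .assemble_corpus(config, iid = FALSE)
  res <- structure(list(sequences = out$sequences, names = out$names,
                        truth = .sim_truth(config), config = config),
                   class = "sim_corpus")
  .write_sim(res, fasta_path, truth_path)
  res
}

#' Simulate a null corpus (no tRNA-state memory)
#'
#' As [simulate_corpus()] but codons are drawn i.i.d. from each family's
#' stationary emission distribution: same marginal codon frequencies, no
#' consecutive-codon structure. This is the null for signal-detection
#' tests.
#'
#' @inheritParams simulate_corpus
#' @return a `sim_corpus`.
#' @export
simulate_null_corpus <- function(config, fasta_path = NULL, truth_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- .assemble_corpus(config, iid = TRUE)
  truth <- .sim_truth(config)
  truth$null <- TRUE
  res <- structure(list(sequences = out$sequences, names = out$names,
                        truth = truth, config = config),
                   class = "sim_corpus")
  .write_sim(res, fasta_path, truth_path)
  res
}

.write_sim <- function(res, fasta_path, truth_path) {
  if (!is.null(fasta_path)) {
    if (length(res$sequences)) {
      x <- Biostrings::DNAStringSet(res$sequences)
      names(x) <- res$names
      Biostrings::writeXStringSet(x, fasta_path)
    } else {
      message("simulated corpus is empty; writing empty FASTA")
      file.create(fasta_path)
    }
  }
  if (!is.null(truth_path)) {
    jsonlite::write_json(res$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf("Simulated corpus: %d genes, %d families%s\n",
              length(x$sequences), length(x$config$readings),
              if (isTRUE(x$truth$null)) " (null, i.i.d. codons)" else ""))
  invisible(x)
}

#' Load a simulated corpus as a `cds_corpus`
#'
#' @param sim a `sim_corpus`.
#' @param policy a `filter_policy`.
#' @return a `cds_corpus`.
#' @export
as_cds_corpus <- function(sim, policy = filter_policy()) {
  stopifnot(inherits(sim, "sim_corpus"))
  corpus_from_strings(sim$sequences, sim$names, code = sim$config$code,
                      policy = policy)
}
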