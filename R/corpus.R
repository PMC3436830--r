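# CDS ingestion and filtering, codon counts, per-gene ordered
# synonymous-codon runs, and consecutive-pair count matrices.

#' CDS filtering policy
#'
#' @param min_length_aa minimum protein length in amino acids, excluding
#'   the terminal stop (default 50).
#' @param reject_internal_stops drop sequences with internal stop codons.
#' @param reject_ambiguous drop sequences with characters outside
#'   \{A, C, G, U/T\} (undetermined nucleotides).
#' @param reject_non_triplet drop sequences whose length is not a
#'   multiple of 3 (the observable proxy for programmed frameshifts in
#'   plain FASTA).
#' @param min_instances_for_pairs minimum occurrences of an amino acid in
#'   a gene for that gene to contribute synonymous runs (default 3).
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_length_aa = 50L,
                          reject_internal_stops = TRUE,
                          reject_ambiguous = TRUE,
                          reject_non_triplet = TRUE,
                          min_instances_for_pairs = 3L) {
  stopifnot(min_length_aa >= 0, min_instances_for_pairs >= 0)
  structure(list(min_length_aa = as.integer(min_length_aa),
                 reject_internal_stops = isTRUE(reject_internal_stops),
                 reject_ambiguous = isTRUE(reject_ambiguous),
                 reject_non_triplet = isTRUE(reject_non_triplet),
                 min_instances_for_pairs = as.integer(min_instances_for_pairs)),
            class = "filter_policy")
}

.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Load and filter a CDS FASTA file
#'
#' Reads coding sequences, normalizes them to the RNA alphabet
#' (case-insensitive; T and U both accepted), strips the terminal stop
#' codon, and applies the filter policy. Each record is either retained
#' or rejected with a reason code: `non_triplet`, `ambiguous`,
#' `internal_stop`, or `short` (checked in that order).
#'
#' @param fasta_path path to a FASTA file of coding sequences.
#' @param code a `genetic_code`.
#' @param policy a `filter_policy`.
#' @return an object of class `cds_corpus`: list with `genes` (named
#'   list of codon character vectors, stop codon removed), `report`
#'   (data frame `record`, `status`, `reason`, `length_aa`), `code`,
#'   and `policy`.
#' @export
load_cds <- function(fasta_path, code = genetic_code(1),
                     policy = filter_policy()) {
  if (!file.exists(fasta_path)) {
    stop(sprintf("FASTA file not found: %s", fasta_path), call. = FALSE)
  }
  seqs <- tryCatch(Biostrings::readBStringSet(fasta_path),
                   error = function(e) stop(sprintf("cannot read FASTA %s: %s",
                                                    fasta_path,
                                                    conditionMessage(e)),
                                            call. = FALSE))
  nm <- names(seqs)
  nm[is.na(nm) | nm == ""] <- paste0("record_", seq_along(nm)[is.na(nm) | nm == ""])
  nm <- vapply(strsplit(nm, "\\s+"), `[[`, character(1), 1L)
  chr <- as_rna(as.character(seqs))
  corpus_from_strings(chr, nm, code = code, policy = policy)
}

#' Build a corpus from in-memory sequences
#'
#' Same contract as [load_cds()] but taking nucleotide strings directly;
#' used by the simulator and by tests.
#'
#' @param seqs character vector of CDS nucleotide strings.
#' @param names record names (default `gene_1`, ...).
#' @param code a `genetic_code`.
#' @param policy a `filter_policy`.
#' @return a `cds_corpus` (see [load_cds()]).
#' @export
corpus_from_strings <- function(seqs, names = NULL, code = genetic_code(1),
                                policy = filter_policy()) {
  stopifnot(inherits(code, "genetic_code"), inherits(policy, "filter_policy"))
  if (is.null(names)) names <- paste0("gene_", seq_along(seqs))
  seqs <- as_rna(seqs)
  genes <- list()
  status <- character(length(seqs))
  reason <- rep(NA_character_, length(seqs))
  length_aa <- rep(NA_integer_, length(seqs))
  stops <- code$stop_codons
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    if (policy$reject_non_triplet && nchar(s) %% 3L != 0L) {
      status[i] <- "rejected"; reason[i] <- "non_triplet"; next
    }
    if (policy$reject_ambiguous && !is_rna(s)) {
      status[i] <- "rejected"; reason[i] <- "ambiguous"; next
    }
    codons <- .split_codons(s)
    # terminal stop codon is stripped before length and stop checks
    if (length(codons) && codons[length(codons)] %in% stops) {
      codons <- codons[-length(codons)]
    }
    if (policy$reject_internal_stops && any(codons %in% stops)) {
      status[i] <- "rejected"; reason[i] <- "internal_stop"; next
    }
    length_aa[i] <- length(codons)
    if (length(codons) < policy$min_length_aa) {
      status[i] <- "rejected"; reason[i] <- "short"; next
    }
    status[i] <- "retained"
    genes[[names[i]]] <- codons
  }
  report <- data.frame(record = names, status = status, reason = reason,
                       length_aa = length_aa, stringsAsFactors = FALSE)
  structure(list(genes = genes, report = report, code = code, policy = policy),
            class = "cds_corpus")
}

#' @export
print.cds_corpus <- function(x, ...) {
  cat(sprintf("CDS corpus: %d retained / %d records\n",
              length(x$genes), nrow(x$report)))
  rej <- table(x$report$reason[x$report$status == "rejected"])
  if (length(rej)) {
    cat("rejections:", paste(sprintf("%s=%d", names(rej), rej), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-gene synonymous-codon runs for one family
#'
#' For each retained gene with at least `min_instances_for_pairs`
#' occurrences of the family's amino acid, the ordered (5' to 3') list of
#' that family's codons, regardless of the spacing between occurrences.
#'
#' @param corpus a `cds_corpus` (or plain named list of codon vectors).
#' @param family an `aa_family` (codon box).
#' @param policy a `filter_policy`; defaults to the corpus's own.
#' @return an object of class `syn_runs`: list with `family` and `runs`
#'   (named list of codon character vectors).
#' @export
build_runs <- function(corpus, family, policy = NULL) {
  genes <- if (inherits(corpus, "cds_corpus")) corpus$genes else corpus
  if (is.null(policy)) {
    policy <- if (inherits(corpus, "cds_corpus")) corpus$policy else filter_policy()
  }
  runs <- lapply(genes, function(codons) codons[codons %in% family$codons])
  runs <- runs[lengths(runs) >= policy$min_instances_for_pairs]
  structure(list(family = family, runs = runs), class = "syn_runs")
}

#' @export
print.syn_runs <- function(x, ...) {
  cat(sprintf("Synonymous runs for %s: %d genes, %d codon occurrences\n",
              x$family$amino_acid, length(x$runs), sum(lengths(x$runs))))
  invisible(x)
}

#' Consecutive synonymous-codon pair counts
#'
#' `X[i, j]` counts the times codon i is followed, at the next occurrence
#' of the same amino acid in the same gene, by codon j. Pairs never cross
#' gene boundaries.
#'
#' @param runs a `syn_runs`.
#' @return an object of class `pair_counts`: list with `family`, `X`
#'   (k x k integer matrix with codon dimnames), and `n_pairs`.
#' @export
count_pairs <- function(runs) {
  stopifnot(inherits(runs, "syn_runs"))
  codons <- runs$family$codons
  k <- length(codons)
  X <- matrix(0L, k, k, dimnames = list(codons, codons))
  for (r in runs$runs) {
    m <- length(r)
    if (m >= 2L) {
      a <- factor(r[-m], levels = codons)
      b <- factor(r[-1L], levels = codons)
      X <- X + table(a, b)
    }
  }
  X <- matrix(as.integer(X), k, k, dimnames = list(codons, codons))
  structure(list(family = runs$family, X = X, n_pairs = sum(X)),
            class = "pair_counts")
}

#' Codon counts per family over a corpus
#'
#' Exact codon tally across all retained genes (no minimum-instance
#' rule; plain frequencies are what the regression method consumes).
#'
#' @param corpus a `cds_corpus` (or plain named list of codon vectors).
#' @param code a `genetic_code`; defaults to the corpus's own.
#' @return an object of class `codon_counts`: named integer vector over
#'   the 61 sense codons (canonical order), with the genetic code as
#'   attribute `code`.
#' @export
count_codons <- function(corpus, code = NULL) {
  genes <- if (inherits(corpus, "cds_corpus")) corpus$genes else corpus
  if (is.null(code)) {
    code <- if (inherits(corpus, "cds_corpus")) corpus$code else genetic_code(1)
  }
  sense <- names(code$codon_to_aa)
  tab <- table(factor(unlist(genes, use.names = FALSE), levels = sense))
  out <- stats::setNames(as.integer(tab), sense)
  structure(out, code = code, class = "codon_counts")
}

#' Counts restricted to one family, in canonical codon order
#'
#' @param counts a `codon_counts` (or any named numeric vector covering
#'   the family's codons).
#' @param family an `aa_family`.
#' @return named numeric vector over `family$codons`.
#' @export
family_counts <- function(counts, family) {
  missing <- setdiff(family$codons, names(counts))
  if (length(missing)) {
    stop(sprintf("counts lack codons: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- as.numeric(counts[family$codons])
  names(out) <- family$codons
  out
}

#' Export codon usage as TSV
#'
#' Writes `family  codon  count` rows for all sense codons.
#'
#' @param counts a `codon_counts`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_codon_usage <- function(counts, path) {
  code <- attr(counts, "code")
  df <- data.frame(family = unname(code$codon_to_aa[names(counts)]),
                   codon = names(counts),
                   count = as.integer(counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codon-usage TSV
#'
#' Counterpart of [write_codon_usage()]: reads `family  codon  count`
#' (or `codon  count`) rows into a named count vector.
#'
#' @param path input file.
#' @param code a `genetic_code` used to validate codons.
#' @return a `codon_counts` vector over the 61 sense codons (codons
#'   absent from the file count 0).
#' @export
read_codon_usage <- function(path, code = genetic_code(1)) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("codon", "count") %in% names(df))) {
    stop("codon-usage table needs 'codon' and 'count' columns", call. = FALSE)
  }
  codon <- as_rna(df$codon)
  bad <- setdiff(codon, names(code$codon_to_aa))
  if (length(bad)) {
    stop(sprintf("unknown sense codon(s) in %s: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- stats::setNames(numeric(length(code$codon_to_aa)),
                         names(code$codon_to_aa))
  out[codon] <- out[codon] + df$count
  structure(out, code = code, class = "codon_counts")
}
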