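# Binary anticodon-codon reading hypotheses: representation, full
# enumeration, plausibility restriction, and the wobble-rule /
# wobble-parsimony baselines.

#' Construct a reading matrix
#'
#' A reading matrix is the binary decoding hypothesis for one amino-acid
#' family (or codon box): rows are tRNA isoacceptors, columns the family's
#' codons in canonical order, and entry 1 means the tRNA can read the
#' codon. Validity requires every tRNA to read at least one codon and
#' every codon to be readable by at least one tRNA.
#'
#' @param family an `aa_family`.
#' @param trnas a `trna_set` restricted to the family.
#' @param reads binary matrix, `nrow(trnas)` x `length(family$codons)`.
#' @param validate check row/column coverage (default TRUE).
#' @return an object of class `reading_matrix`.
#' @export
reading_matrix <- function(family, trnas, reads, validate = TRUE) {
  reads <- as.matrix(reads)
  storage.mode(reads) <- "integer"
  stopifnot(nrow(reads) == nrow(trnas), ncol(reads) == length(family$codons))
  if (!all(reads %in% c(0L, 1L))) {
    stop("reading matrix entries must be 0 or 1", call. = FALSE)
  }
  if (validate) {
    if (any(rowSums(reads) == 0L)) {
      stop("invalid reading: some tRNA reads no codon", call. = FALSE)
    }
    if (any(colSums(reads) == 0L)) {
      stop("invalid reading: some codon is read by no tRNA", call. = FALSE)
    }
  }
  dimnames(reads) <- list(trnas$anticodon, family$codons)
  structure(list(family = family, trnas = trnas, reads = reads),
            class = "reading_matrix")
}

#' Canonical string identifier of a reading
#'
#' Rows are concatenated as bit strings in tRNA order, e.g. `"1100|0011"`.
#'
#' @param reading a `reading_matrix`.
#' @return a single string.
#' @export
reading_id <- function(reading) {
  paste(apply(reading$reads, 1, paste, collapse = ""), collapse = "|")
}

#' @export
print.reading_matrix <- function(x, ...) {
  cat(sprintf("Reading matrix for %s (%d tRNAs x %d codons)\n",
              x$family$amino_acid, nrow(x$reads), ncol(x$reads)))
  print(x$reads)
  invisible(x)
}

#' Test two readings for equality
#' @param a,b `reading_matrix` objects.
#' @return logical.
#' @export
reading_equal <- function(a, b) {
  identical(dim(a$reads), dim(b$reads)) && all(a$reads == b$reads)
}

# non-empty subsets of 1..k as binary rows, ordered by integer mask
.row_masks <- function(k) {
  masks <- 1:(2^k - 1)
  m <- matrix(0L, length(masks), k)
  for (j in seq_len(k)) m[, j] <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L
  storage.mode(m) <- "integer"
  m
}

#' Enumerate all valid binary readings of a family
#'
#' Generates every binary tRNA x codon matrix in which each tRNA reads at
#' least one codon and each codon is read by at least one tRNA, and flags
#' the subset that is plausible under a wobble-option configuration.
#'
#' @param family an `aa_family` (single codon box).
#' @param trnas a `trna_set` for the family; at least one tRNA.
#' @param options wobble-option configuration used for the plausibility
#'   flags (default [default_wobble_options()]); pass `NULL` to skip
#'   flagging.
#' @param max_size guard on the number of candidate matrices
#'   (`(2^k - 1)^n`); larger spaces raise an error.
#' @return an object of class `solution_space`: list with `family`,
#'   `trnas`, `readings` (list of `reading_matrix`), `ids`, and
#'   `plausible` (logical vector).
#' @export
enumerate_all_readings <- function(family, trnas,
                                   options = default_wobble_options(),
                                   max_size = 2^21) {
  stopifnot(inherits(family, "aa_family"))
  n <- nrow(trnas)
  k <- length(family$codons)
  if (n < 1L) stop("no tRNAs for family", call. = FALSE)
  n_cand <- (2^k - 1)^n
  if (n_cand > max_size) {
    stop(sprintf("solution space too large to enumerate (%g candidate matrices)",
                 n_cand), call. = FALSE)
  }
  rows <- .row_masks(k)
  idx <- do.call(expand.grid, rep(list(seq_len(nrow(rows))), n))
  readings <- vector("list", nrow(idx))
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    m <- rows[unlist(idx[i, ]), , drop = FALSE]
    if (all(colSums(m) > 0L)) {
      keep[i] <- TRUE
      readings[[i]] <- reading_matrix(family, trnas, m, validate = FALSE)
    }
  }
  readings <- readings[keep]
  ids <- vapply(readings, reading_id, character(1))
  plausible <- if (is.null(options)) {
    rep(NA, length(readings))
  } else {
    pl_ids <- tryCatch(
      vapply(plausible_readings(family, trnas, options), reading_id, character(1)),
      error = function(e) character(0))
    ids %in% pl_ids
  }
  structure(list(family = family, trnas = trnas, readings = readings,
                 ids = ids, plausible = plausible),
            class = "solution_space")
}

#' @export
print.solution_space <- function(x, ...) {
  cat(sprintf("Solution space for %s: %d valid readings (%s plausible)\n",
              x$family$amino_acid, length(x$readings),
              if (all(is.na(x$plausible))) "un-flagged" else sum(x$plausible)))
  invisible(x)
}

#' Default wobble-option sets
#'
#' For each wobble base (first anticodon position), the alternative sets
#' of codon third bases a tRNA may read. C and G wobble bases are fixed
#' by nucleotide chemistry (C:G only; G reads both pyrimidines), while A
#' (frequently modified to inosine) and U (target of several chemical
#' modifications) admit multiple experimentally observed readings. Every
#' option set contains the Watson-Crick partner of the wobble base.
#'
#' The shipped configuration is read from
#' `inst/extdata/wobble_options.yaml`; supply your own file to
#' [read_wobble_options()] to override.
#'
#' @return named list (by wobble base) of lists of character vectors of
#'   third-position bases.
#' @export
default_wobble_options <- function() {
  read_wobble_options(system.file("extdata", "wobble_options.yaml",
                                  package = "wobblescan", mustWork = TRUE))
}

#' Read a wobble-option configuration
#'
#' @param path YAML file keyed by wobble base; values are lists of
#'   third-position base sets.
#' @return validated named list of option sets.
#' @export
read_wobble_options <- function(path) {
  raw <- yaml::read_yaml(path)
  opts <- lapply(raw, function(sets) lapply(sets, function(s) as_rna(as.character(s))))
  names(opts) <- as_rna(names(opts))
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  for (b in names(opts)) {
    if (length(opts[[b]]) == 0L) {
      stop(sprintf("wobble base %s has no option sets", b), call. = FALSE)
    }
    for (s in opts[[b]]) {
      if (length(s) == 0L || !all(is_rna(s))) {
        stop(sprintf("invalid option set for wobble base %s", b), call. = FALSE)
      }
      if (!(wc[[b]] %in% s)) {
        stop(sprintf("option set {%s} for wobble base %s lacks its Watson-Crick partner %s",
                     paste(s, collapse = ","), b, wc[[b]]), call. = FALSE)
      }
    }
  }
  if ("C" %in% names(opts)) {
    if (!identical(lapply(opts$C, sort), list("G"))) {
      stop("wobble base C admits only cognate binding C:G", call. = FALSE)
    }
  }
  if ("G" %in% names(opts)) {
    if (!identical(lapply(opts$G, sort), list(c("C", "U")))) {
      stop("wobble base G constitutively reads the pyrimidines {C, U}", call. = FALSE)
    }
  }
  opts
}

.reads_from_third_bases <- function(family, third_bases) {
  as.integer(substr(family$codons, 3, 3) %in% third_bases)
}

#' Plausible readings of a family
#'
#' The plausible solution subset: one candidate reading per combination
#' of per-tRNA wobble options (each tRNA reads exactly the codons of its
#' box whose third base falls in the chosen option set), keeping only
#' combinations in which every codon is covered and every tRNA reads at
#' least one codon. Duplicate matrices arising from different option
#' choices are collapsed.
#'
#' @param family an `aa_family` (single codon box).
#' @param trnas a `trna_set` for the family.
#' @param options wobble-option configuration (see
#'   [default_wobble_options()]).
#' @return list of `reading_matrix` objects.
#' @export
plausible_readings <- function(family, trnas,
                               options = default_wobble_options()) {
  n <- nrow(trnas)
  if (n < 1L) stop("no tRNAs for family", call. = FALSE)
  per_trna <- lapply(seq_len(n), function(i) {
    b <- trnas$wobble_base[i]
    if (is.null(options[[b]])) {
      stop(sprintf("no wobble options configured for wobble base %s", b),
           call. = FALSE)
    }
    lapply(options[[b]], function(s) .reads_from_third_bases(family, s))
  })
  combos <- do.call(expand.grid, lapply(per_trna, function(x) seq_along(x)))
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(combos))) {
    m <- do.call(rbind, lapply(seq_len(n), function(j) per_trna[[j]][[combos[i, j]]]))
    if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) next
    r <- reading_matrix(family, trnas, m, validate = FALSE)
    id <- reading_id(r)
    if (!(id %in% seen)) {
      seen <- c(seen, id)
      out[[length(out) + 1L]] <- r
    }
  }
  if (length(out) == 0L) {
    uncovered <- family$codons
    stop(sprintf("no plausible reading covers the codons of %s (uncovered: %s)",
                 family$amino_acid, paste(uncovered, collapse = ", ")),
         call. = FALSE)
  }
  out
}

# Crick wobble rules: allowed codon third bases per anticodon wobble base.
# In the original rules an A at the wobble position is treated as its
# inosine-modified form I:{A, C, U}; the restricted (eukaryote) variant
# disallows the I:A pairing.
.wobble_rule_sets <- function(variant = c("original", "restricted")) {
  variant <- match.arg(variant)
  sets <- list(A = c("A", "C", "U"), C = "G", G = c("C", "U"), U = c("A", "G"))
  if (variant == "restricted") sets$A <- c("C", "U")
  sets
}

#' Reading assigned by Crick's wobble rules
#'
#' Deterministic baseline: each tRNA reads the codons of its box whose
#' third base is allowed by the wobble rules for its wobble base
#' (A:U treated as inosine I:\{A,C,U\}; C:G; G:\{C,U\}; U:\{A,G\}). The
#' `restricted` variant removes the I:A pairing. If some codon is left
#' unreadable, the matrix is returned with a `coverage_warning` attribute
#' naming the uncovered codons.
#'
#' @param family an `aa_family` (single codon box).
#' @param trnas a `trna_set` for the family.
#' @param variant `"original"` or `"restricted"`.
#' @return a `reading_matrix` (possibly with attribute `coverage_warning`).
#' @export
wobble_rules_reading <- function(family, trnas,
                                 variant = c("original", "restricted")) {
  sets <- .wobble_rule_sets(variant)
  m <- do.call(rbind, lapply(seq_len(nrow(trnas)), function(i) {
    .reads_from_third_bases(family, sets[[trnas$wobble_base[i]]])
  }))
  r <- reading_matrix(family, trnas, m, validate = FALSE)
  uncovered <- family$codons[colSums(m) == 0L]
  if (length(uncovered)) {
    attr(r, "coverage_warning") <- uncovered
    warning(sprintf("wobble rules leave codon(s) %s of %s unreadable",
                    paste(uncovered, collapse = ", "), family$amino_acid),
            call. = FALSE)
  }
  r
}

#' Reading assigned by wobble parsimony
#'
#' The eukaryote-specific three-pass heuristic: (i) codons with a cognate
#' (Watson-Crick) tRNA get canonical decoding only; (ii) codons without a
#' cognate tRNA are assigned by restricted wobbling (G:U and, via
#' inosine, A:C); (iii) codons still unassigned get the extended pairings
#' (A:A and U:G). Later passes never add readings to codons already
#' covered by an earlier pass.
#'
#' @param family an `aa_family` (single codon box).
#' @param trnas a `trna_set` for the family.
#' @param mode `"eukaryote"` (the only supported mode; `"prokaryote"`
#'   raises an error, as the heuristic does not apply to bacteria).
#' @return a `reading_matrix` (attribute `coverage_warning` if codons
#'   remain uncovered).
#' @export
wobble_parsimony_reading <- function(family, trnas,
                                     mode = c("eukaryote", "prokaryote")) {
  mode <- match.arg(mode)
  if (mode == "prokaryote") {
    stop("wobble parsimony is only applicable for eukaryotes", call. = FALSE)
  }
  k <- length(family$codons)
  n <- nrow(trnas)
  third <- substr(family$codons, 3, 3)
  wb <- trnas$wobble_base
  m <- matrix(0L, n, k)
  # pass 1: canonical decoding where a cognate tRNA exists
  cognates <- cognate_codon(trnas$anticodon)
  for (i in seq_len(n)) m[i, family$codons == cognates[i]] <- 1L
  covered <- colSums(m) > 0L
  # pass 2: restricted wobbling (G:U, I(A):C) for codons with no cognate
  pass2 <- list(G = "U", A = "C")
  for (i in seq_len(n)) {
    allowed <- pass2[[wb[i]]]
    if (!is.null(allowed)) {
      gain <- !covered & third %in% allowed
      m[i, gain] <- 1L
    }
  }
  covered2 <- colSums(m) > 0L
  # pass 3: extended pairings (A:A, U:G) for codons still unassigned
  pass3 <- list(A = "A", U = "G")
  for (i in seq_len(n)) {
    allowed <- pass3[[wb[i]]]
    if (!is.null(allowed)) {
      gain <- !covered2 & third %in% allowed
      m[i, gain] <- 1L
    }
  }
  r <- reading_matrix(family, trnas, m, validate = FALSE)
  uncovered <- family$codons[colSums(m) == 0L]
  if (length(uncovered)) {
    attr(r, "coverage_warning") <- uncovered
    warning(sprintf("wobble parsimony leaves codon(s) %s of %s unreadable",
                    paste(uncovered, collapse = ", "), family$amino_acid),
            call. = FALSE)
  }
  r
}
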