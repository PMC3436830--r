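# Genetic-code and nucleotide bookkeeping: codons, amino-acid families,
# anticodon/codon complementarity, tRNA isoacceptor tables.
#
# All sequences are handled internally in the RNA alphabet {A, C, G, U};
# DNA input (T) is transliterated on ingestion.

RNA_BASES <- c("U", "C", "A", "G")

# canonical base order U < C < A < G at every codon position
.base_rank <- c(U = 1L, C = 2L, A = 3L, G = 4L)

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and transliterates T to U. Characters outside
#' \{A, C, G, U\} after transliteration are left in place (callers
#' validate with [is_rna()]).
#'
#' @param x character vector of nucleotide strings (DNA or RNA, any case).
#' @return character vector over the RNA alphabet.
#' @export
as_rna <- function(x) {
  chartr("tT", "uU", toupper(chartr("Tt", "Uu", x)))
}

is_rna <- function(x) {
  !is.na(x) & grepl("^[ACGU]+$", x)
}

.check_rna <- function(x, what = "sequence") {
  bad <- !is_rna(as_rna(x))
  if (any(bad)) {
    stop(sprintf("invalid %s alphabet: %s (allowed: A, C, G, U/T)",
                 what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Watson-Crick complement of RNA bases
#' @param x character vector of RNA strings.
#' @return complemented strings (not reversed).
#' @keywords internal
rna_complement <- function(x) {
  chartr("ACGU", "UGCA", x)
}

.reverse_string <- function(x) {
  vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), character(1))
}

#' Reverse complement of an RNA string
#' @param x character vector of RNA strings.
#' @return reverse-complemented strings.
#' @export
rna_reverse_complement <- function(x) {
  .reverse_string(rna_complement(x))
}

#' Cognate codon of an anticodon
#'
#' The codon read by strict Watson-Crick (cognate) pairing: codon and
#' anticodon bind antiparallel, so codon position 3 pairs with anticodon
#' position 1 (the wobble position). The cognate codon is therefore the
#' reverse complement of the anticodon.
#'
#' @param anticodon character vector of 3-letter anticodons, 5' to 3'
#'   (DNA or RNA; T is accepted and converted).
#' @return character vector of codons (RNA).
#' @examples
#' cognate_codon("AGC")  # "GCU", alanine
#' @export
cognate_codon <- function(anticodon) {
  anticodon <- as_rna(anticodon)
  .check_rna(anticodon, "anticodon")
  if (any(nchar(anticodon) != 3L)) {
    stop("anticodons must be exactly 3 nucleotides", call. = FALSE)
  }
  rna_reverse_complement(anticodon)
}

#' All 64 codons in canonical order
#'
#' Canonical order is U < C < A < G at each position, varying the third
#' position fastest; this fixes matrix row/column order throughout the
#' package.
#'
#' @return character vector of 64 RNA codons.
#' @export
all_codons <- function() {
  g <- expand.grid(p3 = RNA_BASES, p2 = RNA_BASES, p1 = RNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

.codon_order <- function(codons) {
  m <- do.call(rbind, strsplit(codons, ""))
  order(.base_rank[m[, 1]], .base_rank[m[, 2]], .base_rank[m[, 3]])
}

#' Build a genetic-code object
#'
#' Wraps an NCBI translation table (via [Biostrings::getGeneticCode()])
#' into a validated map from the sense codons to one-letter amino acids
#' plus the stop-codon set, in the package's RNA alphabet and canonical
#' codon order.
#'
#' @param table_id NCBI translation table identifier (integer or string);
#'   default 1, the standard code.
#' @return an object of class `genetic_code` with elements `table_id`,
#'   `codon_to_aa` (named character, sense codons only), `stop_codons`,
#'   and `amino_acids`.
#' @export
genetic_code <- function(table_id = 1) {
  raw <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- as_rna(names(raw))
  ord <- .codon_order(codons)
  codons <- codons[ord]
  aa <- unname(raw[ord])
  stops <- codons[aa == "*"]
  sense <- aa != "*"
  obj <- list(
    table_id = as.integer(table_id),
    codon_to_aa = stats::setNames(aa[sense], codons[sense]),
    stop_codons = stops,
    amino_acids = sort(unique(aa[sense]))
  )
  stopifnot(length(obj$codon_to_aa) + length(obj$stop_codons) == 64L)
  class(obj) <- "genetic_code"
  obj
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code (NCBI table %d): %d sense codons, %d stop codons, %d amino acids\n",
              x$table_id, length(x$codon_to_aa), length(x$stop_codons),
              length(x$amino_acids)))
  invisible(x)
}

# three-letter to one-letter amino acid names, for tRNA table parsing
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", SeC = "U", Sec = "U", Sup = "*"
)

.normalize_aa <- function(aa) {
  aa <- as.character(aa)
  out <- ifelse(nchar(aa) == 1L, toupper(aa),
                unname(AA_THREE_TO_ONE[paste0(
                  toupper(substr(aa, 1, 1)), tolower(substr(aa, 2, 10)))]))
  if (any(is.na(out))) {
    stop(sprintf("unknown amino acid name(s): %s",
                 paste(unique(aa[is.na(out)]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Synonymous-codon family of an amino acid
#'
#' @param code a `genetic_code` object.
#' @param amino_acid one-letter (or three-letter) amino-acid code.
#' @return an object of class `aa_family` with elements `amino_acid` and
#'   `codons` (canonical order).
#' @export
family_of <- function(code, amino_acid) {
  stopifnot(inherits(code, "genetic_code"))
  aa <- .normalize_aa(amino_acid)
  codons <- names(code$codon_to_aa)[code$codon_to_aa == aa]
  if (length(codons) == 0L) {
    stop(sprintf("amino acid '%s' not found in genetic code table %d",
                 amino_acid, code$table_id), call. = FALSE)
  }
  structure(list(amino_acid = aa, codons = codons), class = "aa_family")
}

#' @export
print.aa_family <- function(x, ...) {
  cat(sprintf("Amino-acid family %s: {%s}\n", x$amino_acid,
              paste(x$codons, collapse = ", ")))
  invisible(x)
}

.family_box_prefixes <- function(family) {
  unique(substr(family$codons, 1, 2))
}

#' Split a family into codon boxes
#'
#' A codon box is the subset of a family sharing codon positions 1-2.
#' Six-codon families (Ser, Leu, Arg in the standard code) span two boxes
#' that are decoded independently (cross-box reading is excluded), so
#' enumeration and scoring operate per box.
#'
#' @param family an `aa_family`.
#' @return list of `aa_family` objects, one per box, named
#'   `"<aa>/<prefix>N"`; families occupying a single box are returned
#'   as-is in a length-1 list.
#' @export
family_boxes <- function(family) {
  stopifnot(inherits(family, "aa_family"))
  prefixes <- .family_box_prefixes(family)
  if (length(prefixes) == 1L) {
    out <- list(family)
    names(out) <- family$amino_acid
    return(out)
  }
  out <- lapply(prefixes, function(p) {
    structure(list(amino_acid = family$amino_acid,
                   codons = family$codons[substr(family$codons, 1, 2) == p],
                   box = p),
              class = "aa_family")
  })
  names(out) <- paste0(family$amino_acid, "/", prefixes, "N")
  out
}

#' Construct a tRNA isoacceptor set
#'
#' @param amino_acid vector of amino-acid codes (one- or three-letter).
#' @param anticodon vector of 3-letter anticodons (DNA or RNA).
#' @param copies non-negative gene copy numbers (abundance proxy).
#' @return a data frame of class `trna_set` with columns `amino_acid`,
#'   `anticodon`, `copies`, `wobble_base` (first, 5', anticodon base).
#'   Duplicate (amino acid, anticodon) entries have their copies summed.
#' @export
trna_set <- function(amino_acid, anticodon, copies) {
  if (length(amino_acid) == 0L) {
    out <- data.frame(amino_acid = character(), anticodon = character(),
                      copies = integer(), wobble_base = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("trna_set", "data.frame")
    return(out)
  }
  aa <- .normalize_aa(amino_acid)
  ac <- as_rna(anticodon)
  .check_rna(ac, "anticodon")
  if (any(nchar(ac) != 3L)) {
    stop("anticodons must be exactly 3 nucleotides", call. = FALSE)
  }
  copies <- as.numeric(copies)
  if (any(is.na(copies)) || any(copies < 0)) {
    stop("gene copy numbers must be non-negative", call. = FALSE)
  }
  agg <- stats::aggregate(copies, by = list(amino_acid = aa, anticodon = ac), FUN = sum)
  names(agg)[3] <- "copies"
  agg$wobble_base <- substr(agg$anticodon, 1, 1)
  agg <- agg[order(agg$amino_acid, agg$anticodon), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("trna_set", "data.frame")
  agg
}

#' Parse a tRNA isoacceptor table
#'
#' Reads a delimited text file in the style of Genomic tRNA Database
#' exports, with header columns `amino_acid`, `anticodon`, `copies`
#' (tab- or whitespace-separated). Duplicate (amino acid, anticodon)
#' rows are summed.
#'
#' @param path path to the table.
#' @return a `trna_set`.
#' @export
parse_trna_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("tRNA table not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(trna_set(character(), character(), integer()))
  fields <- strsplit(trimws(lines), "[\t ]+")
  header <- tolower(fields[[1]])
  has_header <- any(c("amino_acid", "anticodon", "copies") %in% header)
  rows <- if (has_header) fields[-1] else fields
  if (length(rows) == 0L) return(trna_set(character(), character(), integer()))
  nf <- lengths(rows)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1] + has_header
    stop(sprintf("malformed tRNA table row at line %d of %s (expected 3 columns)",
                 bad, path), call. = FALSE)
  }
  aa <- vapply(rows, `[[`, character(1), 1L)
  ac <- vapply(rows, `[[`, character(1), 2L)
  cp <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L)))
  if (any(is.na(cp))) {
    bad <- which(is.na(cp))[1] + has_header
    stop(sprintf("non-numeric copy number at line %d of %s", bad, path),
         call. = FALSE)
  }
  trna_set(aa, ac, cp)
}

#' Subset a tRNA set to one amino-acid family (or codon box)
#'
#' When `family` carries a box (from [family_boxes()]), only isoacceptors
#' whose anticodon positions 2-3 are cognate to the box's codon positions
#' 1-2 are kept.
#'
#' @param trnas a `trna_set`.
#' @param family an `aa_family`.
#' @return a `trna_set` restricted to the family.
#' @export
trnas_for_family <- function(trnas, family) {
  stopifnot(inherits(trnas, "trna_set"), inherits(family, "aa_family"))
  sel <- trnas$amino_acid == family$amino_acid
  out <- trnas[sel, , drop = FALSE]
  if (nrow(out)) {
    # anticodon positions 2-3 reverse-complement to codon positions 1-2
    prefix <- rna_reverse_complement(substr(out$anticodon, 2, 3))
    keep <- prefix %in% unique(substr(family$codons, 1, 2))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("trna_set", "data.frame")
  out
}
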