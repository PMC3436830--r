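# Regression method: tRNA gene copy number against a quadratic function
# of summed, sharing-normalized codon counts, fitted through the origin.

#' Sharing-normalization weights of a reading
#'
#' When several tRNAs read the same codon, each is allocated a fraction
#' of the codon's counts. A tRNA reading `k_i` different codons claims a
#' share proportional to `1/k_i`, so for codon c read by tRNA i the
#' weight is `n_ci = (1/k_i) / sum_j (1/k_j)` over all tRNAs j reading c.
#' Weights over each codon sum to one (counts are conserved).
#'
#' @param reading a `reading_matrix`.
#' @return numeric matrix (tRNAs x codons); zero where the tRNA does not
#'   read the codon, columns summing to 1.
#' @export
sharing_weights <- function(reading) {
  reads <- reading$reads
  inv_k <- 1 / rowSums(reads)
  num <- reads * inv_k
  denom <- colSums(num)
  W <- sweep(num, 2, denom, "/")
  dimnames(W) <- dimnames(reads)
  W
}

#' Summed codon counts per tRNA under a reading
#'
#' `x_i = sum_c n_ci * count(c)` over the codons tRNA i reads. Summing
#' over tRNAs recovers the total family count exactly.
#'
#' @param reading a `reading_matrix`.
#' @param counts a `codon_counts` or named numeric vector covering the
#'   family's codons.
#' @return named numeric vector (one entry per tRNA, anticodon names).
#' @export
summed_counts <- function(reading, counts) {
  cnt <- family_counts(counts, reading$family)
  x <- drop(sharing_weights(reading) %*% cnt)
  names(x) <- reading$trnas$anticodon
  x
}

#' Through-origin quadratic least squares
#'
#' Fits `y = gamma * x^2 + e` with no intercept: the closed form is
#' `gamma = sum(x^2 y) / sum(x^4)`. The fit quality is the uncentered
#' coefficient of determination `R^2 = 1 - SS_res / sum(y^2)` (the
#' centered variant, `1 - SS_res / sum((y - mean(y))^2)`, is available
#' behind a flag; it can be negative for a through-origin model).
#'
#' @param x summed codon counts per tRNA.
#' @param y tRNA gene copy numbers.
#' @param centered use the centered R^2 variant (default FALSE).
#' @return list with `gamma`, `r_squared`, `fitted`, `residuals`.
#' @export
fit_quadratic_origin <- function(x, y, centered = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (all(x == 0)) {
    stop("undefined fit: all summed codon counts are zero", call. = FALSE)
  }
  x2 <- x^2
  gamma <- sum(x2 * y) / sum(x2^2)
  fitted <- gamma * x2
  res <- y - fitted
  ss_res <- sum(res^2)
  ss_tot <- if (centered) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(gamma = gamma, r_squared = r2, fitted = fitted, residuals = res)
}

#' Regression score of a reading hypothesis
#'
#' Composes [sharing_weights()], [summed_counts()] and
#' [fit_quadratic_origin()]; the reading with the highest `R^2` is the
#' regression method's prediction. tRNAs with zero gene copies are
#' excluded from the fit (their abundance proxy is undefined). Families
#' with a single tRNA carry no regression information and are flagged
#' trivial (`r_squared = NA`).
#'
#' @param reading a `reading_matrix`.
#' @param counts codon counts covering the family.
#' @param centered passed to [fit_quadratic_origin()].
#' @return an object of class `reg_fit`: list with `reading`, `x`,
#'   `copies`, `gamma`, `r_squared`, `residuals`, `trivial`.
#' @export
score_reading_reg <- function(reading, counts, centered = FALSE) {
  x <- summed_counts(reading, counts)
  y <- as.numeric(reading$trnas$copies)
  keep <- y > 0
  if (sum(keep) < 2L) {
    return(structure(list(reading = reading, x = x, copies = y,
                          gamma = NA_real_, r_squared = NA_real_,
                          residuals = NULL, trivial = TRUE),
                     class = "reg_fit"))
  }
  fit <- fit_quadratic_origin(x[keep], y[keep], centered = centered)
  structure(list(reading = reading, x = x, copies = y,
                 gamma = fit$gamma, r_squared = fit$r_squared,
                 residuals = fit$residuals, trivial = FALSE),
            class = "reg_fit")
}

#' @export
print.reg_fit <- function(x, ...) {
  if (x$trivial) {
    cat(sprintf("Regression fit %s: trivial (fewer than 2 tRNAs with copies)\n",
                reading_id(x$reading)))
  } else {
    cat(sprintf("Regression fit %s: gamma = %.4g, R^2 = %.4f\n",
                reading_id(x$reading), x$gamma, x$r_squared))
  }
  invisible(x)
}
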