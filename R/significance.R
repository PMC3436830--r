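# Score normalization over solution spaces, randomized null corpora,
# Monte-Carlo empirical p-values, and cross-method consensus tallies.

#' Min-max normalization of scores
#'
#' Affine map of scores to [0, 1]: `s_n = (s - min s) / (max s - min s)`.
#' When all scores are equal the map is degenerate; all values are set
#' to 0.5 and the result carries attribute `degenerate = TRUE`.
#'
#' @param scores numeric vector (at least 2 values for a non-degenerate
#'   map).
#' @return numeric vector in [0, 1], names preserved.
#' @export
normalize_scores <- function(scores) {
  scores <- as.numeric(scores)
  rng <- range(scores, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    out <- rep(0.5, length(scores))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  pmin(pmax((scores - rng[1]) / (rng[2] - rng[1]), 0), 1)
}

#' Randomize synonymous runs
#'
#' The null corpus for the HMM and CC methods: every gene keeps its run
#' length (the amino-acid sequence is untouched) but the codons are
#' drawn i.i.d. from the family's corpus-wide codon frequencies,
#' removing any consecutive-codon structure.
#'
#' @param runs a `syn_runs`.
#' @param counts codon counts covering the family (source of the
#'   frequencies).
#' @param seed optional integer seed for reproducibility.
#' @return a `syn_runs` of the same shape with randomized codons.
#' @export
randomize_runs <- function(runs, counts, seed = NULL) {
  stopifnot(inherits(runs, "syn_runs"))
  if (!is.null(seed)) set.seed(seed)
  cnt <- family_counts(counts, runs$family)
  if (sum(cnt) <= 0) stop("no codon counts for family", call. = FALSE)
  p <- cnt / sum(cnt)
  codons <- runs$family$codons
  lens <- lengths(runs$runs)
  total <- sum(lens)
  draw <- sample(codons, total, replace = TRUE, prob = p)
  out <- runs
  out$runs <- split(draw, rep(seq_along(lens), lens))
  names(out$runs) <- names(runs$runs)
  out
}

# Moment-matched skew-normal parameters (location xi, scale omega,
# shape delta in (-1, 1)) from mean m, sd s and skewness g1.
.skewnormal_params <- function(m, s, g1, max_skew = 0.995) {
  g1 <- max(min(g1, max_skew), -max_skew)
  b <- sqrt(2 / pi)
  cc <- sign(g1) * (2 * abs(g1) / (4 - pi))^(1 / 3)
  u <- cc / sqrt(1 + cc^2)          # u = delta * b / sqrt(1 - b^2 delta^2) inverse
  delta <- u / b
  delta <- max(min(delta, 0.9999), -0.9999)
  omega <- s / sqrt(1 - b^2 * delta^2)
  xi <- m - omega * delta * b
  list(xi = xi, omega = omega, delta = delta)
}

.rskewnormal <- function(n, xi, omega, delta) {
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  xi + omega * z
}

#' Randomized codon counts from a skew-normal null
#'
#' The null for the regression method: each codon's count is replaced
#' by a draw from a skew-normal distribution whose location, scale and
#' shape are moment-matched (mean, variance, skewness) to the family's
#' observed codon-count distribution. Skewness is clamped to the
#' admissible skew-normal range (|skewness| < 0.995); families with
#' fewer than 3 codons fall back to a normal (shape 0). Negative draws
#' are clamped to 0.
#'
#' @param counts codon counts covering the family.
#' @param family an `aa_family`.
#' @param seed optional integer seed.
#' @return named numeric vector of randomized counts over the family's
#'   codons.
#' @export
randomize_counts_skewnormal <- function(counts, family, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- family_counts(counts, family)
  k <- length(cnt)
  m <- mean(cnt)
  s <- stats::sd(cnt)
  if (is.na(s) || s == 0) {
    return(stats::setNames(rep(m, k), names(cnt)))
  }
  g1 <- if (k >= 3L) mean((cnt - m)^3) / (mean((cnt - m)^2))^(3 / 2) else 0
  par <- .skewnormal_params(m, s, g1)
  draws <- .rskewnormal(k, par$xi, par$omega, par$delta)
  stats::setNames(pmax(draws, 0), names(cnt))
}

#' Monte-Carlo empirical p-value
#'
#' Rank-based p-value of a real score against `n` randomized replicate
#' scores: `p = (r + 1) / (n + 1)` where `r` counts null scores greater
#' than or equal to the real score (ties count toward r). A real score
#' beating all 99 replicates gives p = 0.01; ranking second gives 0.02.
#'
#' @param real_score scalar observed score.
#' @param null_scores numeric vector of replicate scores.
#' @return an object of class `empirical_p`: list with `p`, `r`, `n`.
#' @export
empirical_p <- function(real_score, null_scores) {
  if (length(null_scores) == 0L) {
    stop("empty null score set", call. = FALSE)
  }
  stopifnot(length(real_score) == 1L)
  r <- sum(null_scores >= real_score)
  n <- length(null_scores)
  structure(list(p = (r + 1) / (n + 1), r = r, n = n), class = "empirical_p")
}

#' @export
print.empirical_p <- function(x, ...) {
  cat(sprintf("empirical p = %.4g (r = %d of n = %d replicates >= real)\n",
              x$p, x$r, x$n))
  invisible(x)
}

#' Cross-method consensus tally
#'
#' Partitions families by the agreement pattern of the three methods'
#' best plausible readings: all three identical; exactly one pair
#' identical (three such regions); or all distinct. Agreement means
#' exact reading-matrix equality. When null replicates are supplied,
#' each region's expected count and a Monte-Carlo p-value (one-sided in
#' the direction of the observed deviation) are attached.
#'
#' @param predictions named list, one element per family, each a list
#'   with components `hmm`, `reg`, `cc` holding `reading_matrix` objects
#'   (or reading-id strings). Families missing any method are excluded
#'   with a warning.
#' @param null_replicates optional list of replicate prediction lists of
#'   the same structure (predictions under randomized data).
#' @return an object of class `consensus_tally`: list with `counts`
#'   (named integer vector over the five regions), `n_families`, and
#'   (with replicates) `expected` and `p_values`.
#' @export
consensus_tally <- function(predictions, null_replicates = NULL) {
  regions <- c("all_three", "hmm_reg_only", "hmm_cc_only", "reg_cc_only", "none")
  tally_one <- function(preds) {
    ids <- vapply(preds, function(p) {
      keep <- vapply(p[c("hmm", "reg", "cc")], Negate(is.null), logical(1))
      if (!all(keep)) return(NA_character_)
      v <- lapply(p[c("hmm", "reg", "cc")], function(x) {
        if (inherits(x, "reading_matrix")) reading_id(x) else as.character(x)
      })
      h <- v$hmm; r <- v$reg; cc <- v$cc
      if (h == r && r == cc) "all_three"
      else if (h == r) "hmm_reg_only"
      else if (h == cc) "hmm_cc_only"
      else if (r == cc) "reg_cc_only"
      else "none"
    }, character(1))
    ids
  }
  obs <- tally_one(predictions)
  if (anyNA(obs)) {
    warning(sprintf("%d families lack a prediction from some method and are excluded",
                    sum(is.na(obs))), call. = FALSE)
    obs <- obs[!is.na(obs)]
  }
  counts <- stats::setNames(as.integer(table(factor(obs, levels = regions))), regions)
  out <- list(counts = counts, n_families = length(obs))
  if (!is.null(null_replicates) && length(null_replicates)) {
    reps <- vapply(null_replicates, function(r) {
      ids <- tally_one(r)
      as.integer(table(factor(ids[!is.na(ids)], levels = regions)))
    }, integer(length(regions)))
    rownames(reps) <- regions
    expected <- rowMeans(reps)
    p <- vapply(regions, function(g) {
      if (counts[g] >= expected[g]) {
        empirical_p(counts[g], reps[g, ])$p
      } else {
        empirical_p(-counts[g], -reps[g, ])$p
      }
    }, numeric(1))
    out$expected <- expected
    out$p_values <- p
  }
  structure(out, class = "consensus_tally")
}

#' @export
print.consensus_tally <- function(x, ...) {
  cat(sprintf("Consensus over %d families:\n", x$n_families))
  df <- data.frame(region = names(x$counts), count = as.integer(x$counts))
  if (!is.null(x$expected)) {
    df$expected <- round(x$expected, 1)
    df$p <- signif(x$p_values, 3)
  }
  print(df, row.names = FALSE)
  invisible(x)
}
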