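# HMM scoring of reading hypotheses. Hidden states are the tRNA
# isoacceptors of one amino-acid family; the observable is the ordered
# run of synonymous codons in a gene. Emissions are fixed by the reading
# hypothesis, transitions by tRNA abundance plus a diagonal reuse term,
# and the start vector by the stationary distribution; no parameter is
# optimized during evaluation.

#' tRNA reuse parameters of the transition diagonal
#'
#' The self-transition boost added to the transition-matrix diagonal is
#' `max(0, alpha + beta * w_i)` where `w_i` is the relative gene-copy
#' frequency of tRNA i. With `beta < 0` the boost is larger for rare
#' tRNAs. Defaults are the values pre-estimated from yeast data.
#'
#' @param alpha intercept (default 0.065).
#' @param beta gradient against relative tRNA abundance (default -0.087).
#' @return an object of class `reuse_params`.
#' @export
reuse_params <- function(alpha = 0.065, beta = -0.087) {
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "reuse_params")
}

#' @export
print.reuse_params <- function(x, ...) {
  cat(sprintf("Reuse parameters: alpha = %.4g, beta = %.4g\n", x$alpha, x$beta))
  if (!is.null(attr(x, "converged"))) {
    cat(sprintf("  estimated (%s, %d iterations)\n",
                if (attr(x, "converged")) "converged" else "NOT converged",
                nrow(attr(x, "trace"))))
  }
  invisible(x)
}

#' Emission matrix of a reading hypothesis
#'
#' Row i is uniform over the codons tRNA i can read and zero elsewhere,
#' so each row sums to one.
#'
#' @param reading a `reading_matrix`.
#' @return numeric matrix (tRNAs x codons) with dimnames from the reading.
#' @export
build_emissions <- function(reading) {
  reads <- reading$reads
  ki <- rowSums(reads)
  if (any(ki == 0)) {
    stop("invalid reading: some tRNA reads no codon", call. = FALSE)
  }
  E <- reads / ki
  dimnames(E) <- dimnames(reads)
  E
}

#' Transition matrix from tRNA abundances and reuse term
#'
#' With `w_j` the relative gene-copy frequency of tRNA j, off-diagonal
#' entries are proportional to `w_j` (moving to a state is proportional
#' to its abundance) and the diagonal receives the additive reuse boost
#' `max(0, alpha + beta * w_i)` before row renormalization. The matrix is
#' the same for every reading hypothesis of the family.
#'
#' @param trnas a `trna_set` for the family.
#' @param reuse a `reuse_params`.
#' @return row-stochastic numeric matrix (tRNAs x tRNAs).
#' @export
build_transitions <- function(trnas, reuse = reuse_params()) {
  copies <- as.numeric(trnas$copies)
  if (sum(copies) <= 0) {
    stop("degenerate abundances: all tRNA gene copy numbers are zero",
         call. = FALSE)
  }
  w <- copies / sum(copies)
  n <- length(w)
  d <- pmax(0, reuse$alpha + reuse$beta * w)
  T <- matrix(w, n, n, byrow = TRUE)
  diag(T) <- w + d
  T <- T / rowSums(T)
  dimnames(T) <- list(trnas$anticodon, trnas$anticodon)
  T
}

#' Stationary start distribution of a transition matrix
#'
#' The left eigenvector of `T` for eigenvalue 1 (the limiting tRNA
#' usage), normalized to sum to one. If the eigen decomposition does not
#' yield a clean non-negative stationary vector (e.g. a reducible
#' chain), falls back to power iteration with a warning.
#'
#' @param T row-stochastic transition matrix.
#' @return numeric start vector summing to 1.
#' @export
stationary_start <- function(T) {
  n <- nrow(T)
  if (n == 1L) return(stats::setNames(1, rownames(T)))
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- e$vectors[, i]
  if (max(abs(Im(v))) < 1e-9) {
    v <- Re(v)
    v <- v / sum(v)
    if (all(v > -1e-12)) {
      v <- pmax(v, 0)
      v <- v / sum(v)
      if (max(abs(drop(v %*% T) - v)) < 1e-8) {
        names(v) <- rownames(T)
        return(v)
      }
    }
  }
  warning("transition matrix has no clean stationary eigenvector; using power iteration",
          call. = FALSE)
  v <- rep(1 / n, n)
  for (it in 1:10000) {
    v2 <- drop(v %*% T)
    if (max(abs(v2 - v)) < 1e-13) break
    v <- v2
  }
  v <- v / sum(v)
  names(v) <- rownames(T)
  v
}

#' Assemble the HMM of one reading hypothesis
#'
#' @param reading a `reading_matrix`.
#' @param reuse a `reuse_params`.
#' @return an object of class `hmm_model` with elements `E`, `T`, `pi`,
#'   `family`, and `trnas`.
#' @export
hmm_model <- function(reading, reuse = reuse_params()) {
  E <- build_emissions(reading)
  T <- build_transitions(reading$trnas, reuse)
  pi <- stationary_start(T)
  structure(list(E = E, T = T, pi = pi,
                 family = reading$family, trnas = reading$trnas),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("HMM for %s: %d tRNA states, %d codons\n",
              x$family$amino_acid, nrow(x$E), ncol(x$E)))
  invisible(x)
}

.runs_to_indices <- function(runs, codons) {
  lapply(runs, function(r) {
    idx <- match(r, codons)
    if (anyNA(idx)) {
      stop(sprintf("codon(s) outside family: %s",
                   paste(unique(r[is.na(idx)]), collapse = ", ")),
           call. = FALSE)
    }
    idx
  })
}

# Scaled forward recursion, vectorized over runs.
# E: S x k, T: S x S, pi: length S, obs_idx: list of integer vectors.
# Returns one log-likelihood per run; runs in which some codon has zero
# emission mass in every reachable state score -Inf.
.forward_batch <- function(E, T, pi, obs_idx) {
  n <- length(obs_idx)
  if (n == 0L) return(numeric(0))
  lens <- lengths(obs_idx)
  if (any(lens == 0L)) stop("empty run", call. = FALSE)
  maxlen <- max(lens)
  S <- nrow(E)
  obs <- matrix(1L, n, maxlen)
  for (i in seq_len(n)) obs[i, seq_len(lens[i])] <- obs_idx[[i]]
  tE <- unname(t(E))  # k x S
  A <- matrix(pi, n, S, byrow = TRUE) * tE[obs[, 1L], , drop = FALSE]
  sc <- rowSums(A)
  ll <- ifelse(sc > 0, log(sc), -Inf)
  A <- A / ifelse(sc > 0, sc, 1)
  if (maxlen >= 2L) {
    for (t in 2:maxlen) {
      act <- which(lens >= t & is.finite(ll))
      if (length(act) == 0L) next
      Anew <- (A[act, , drop = FALSE] %*% T) * tE[obs[act, t], , drop = FALSE]
      sc <- rowSums(Anew)
      pos <- sc > 0
      ll[act] <- ll[act] + ifelse(pos, log(sc), -Inf)
      A[act, ] <- Anew / ifelse(pos, sc, 1)
    }
  }
  ll
}

#' Forward log-likelihood of a synonymous-codon run
#'
#' `log P(O | lambda)` by the scaled forward recursion; numerically
#' stable for long runs. Returns `-Inf` when some observed codon has
#' zero emission probability in every state with positive mass.
#'
#' @param model an `hmm_model`.
#' @param run character vector of codons (all within the model's
#'   family), or an integer vector of codon indices.
#' @return scalar log-probability (<= 0).
#' @export
forward_log_prob <- function(model, run) {
  stopifnot(inherits(model, "hmm_model"))
  idx <- if (is.numeric(run)) list(as.integer(run))
         else .runs_to_indices(list(as_rna(run)), model$family$codons)
  .forward_batch(model$E, model$T, model$pi, idx)
}

#' Total HMM score of a reading hypothesis
#'
#' The sum over all runs of the forward log-likelihood under the model
#' built from the reading. No HMM parameter is optimized during
#' evaluation; the reading with the highest total is the inferred codon
#' reading.
#'
#' @param reading a `reading_matrix`.
#' @param runs a `syn_runs` (or plain list of codon vectors).
#' @param reuse a `reuse_params`.
#' @param model optional pre-built `hmm_model` (to share `T` and `pi`
#'   across readings, only `E` is rebuilt when `model` is given).
#' @return an object of class `hmm_score`: list with `reading`,
#'   `total_log_prob`, and `n_runs`.
#' @export
score_reading_hmm <- function(reading, runs, reuse = reuse_params(),
                              model = NULL) {
  run_list <- if (inherits(runs, "syn_runs")) runs$runs else runs
  if (length(run_list) == 0L) {
    return(structure(list(reading = reading, total_log_prob = 0, n_runs = 0L),
                     class = "hmm_score"))
  }
  if (is.null(model)) {
    model <- hmm_model(reading, reuse)
  } else {
    model$E <- build_emissions(reading)
  }
  idx <- .runs_to_indices(run_list, reading$family$codons)
  ll <- .forward_batch(model$E, model$T, model$pi, idx)
  structure(list(reading = reading, total_log_prob = sum(ll),
                 n_runs = length(run_list)),
            class = "hmm_score")
}

#' @export
print.hmm_score <- function(x, ...) {
  cat(sprintf("HMM score %s: total log P = %.4f over %d runs\n",
              reading_id(x$reading), x$total_log_prob, x$n_runs))
  invisible(x)
}

# Viterbi decoding, vectorized forward pass, per-run backtrace.
# Ties are broken toward the lower state index (max.col ties = "first").
.viterbi_batch <- function(E, T, pi, obs_idx) {
  n <- length(obs_idx)
  if (n == 0L) return(list())
  lens <- lengths(obs_idx)
  maxlen <- max(lens)
  S <- nrow(E)
  obs <- matrix(1L, n, maxlen)
  for (i in seq_len(n)) obs[i, seq_len(lens[i])] <- obs_idx[[i]]
  logE <- unname(log(t(E)))  # k x S
  logT <- unname(log(T))
  V <- matrix(log(pi), n, S, byrow = TRUE) + logE[obs[, 1L], , drop = FALSE]
  ptr <- if (maxlen >= 2L) array(1L, dim = c(n, S, maxlen)) else NULL
  if (maxlen >= 2L) {
    for (t in 2:maxlen) {
      Vnew <- matrix(-Inf, n, S)
      for (s in seq_len(S)) {
        cand <- V + matrix(logT[, s], n, S, byrow = TRUE)
        best <- max.col(cand, ties.method = "first")
        Vnew[, s] <- cand[cbind(seq_len(n), best)] + logE[obs[, t], s]
        ptr[, s, t] <- best
      }
      upd <- lens >= t
      V[upd, ] <- Vnew[upd, , drop = FALSE]
      if (!is.null(ptr)) {
        # rows already past their run length keep their final V; pointers
        # for t > len are never read in backtrace
      }
    }
  }
  # NOTE: V rows for runs shorter than maxlen were overwritten only while
  # active, so each row holds the value at its own final position.
  paths <- vector("list", n)
  final_state <- max.col(V, ties.method = "first")
  for (i in seq_len(n)) {
    L <- lens[i]
    p <- integer(L)
    p[L] <- final_state[i]
    if (L >= 2L) {
      for (t in L:2L) p[t - 1L] <- ptr[i, p[t], t]
    }
    paths[[i]] <- p
  }
  paths
}

#' Viterbi state paths for a set of runs
#'
#' Most likely tRNA-state sequence for each run; ties broken toward the
#' lower state index.
#'
#' @param model an `hmm_model`.
#' @param runs a `syn_runs` or list of codon vectors.
#' @return list of integer state-path vectors.
#' @export
viterbi_paths <- function(model, runs) {
  run_list <- if (inherits(runs, "syn_runs")) runs$runs else runs
  idx <- .runs_to_indices(run_list, model$family$codons)
  .viterbi_batch(model$E, model$T, model$pi, idx)
}

#' Estimate the reuse parameters from data
#'
#' Iterative procedure: from the current (alpha, beta) build the
#' transition matrix, Viterbi-decode all runs under a fixed reference
#' reading (default: the restricted wobble-rules reading, which is
#' neutral with respect to the hypotheses later scored), tally the
#' self-transition frequency of every state, convert it to the implied
#' diagonal excess `d_i = (f_i - w_i) / (1 - f_i)`, and update
#' (alpha, beta) by weighted least squares of `d_i` on `w_i`. Stops when
#' both parameter changes fall below `tol` (the converged parameters are
#' returned; with `tol = Inf` the initial values are returned unchanged
#' after a single pass) or after `max_iter` iterations (flagged
#' non-converged).
#'
#' Estimation pools all supplied families (global estimate); pass a
#' single family's runs for a per-family estimate.
#'
#' @param runs a `syn_runs`, or a list of `syn_runs` over families.
#' @param trnas a `trna_set` covering the families of `runs`.
#' @param init initial `reuse_params` (default alpha = 0, beta = 0, i.e.
#'   a transition matrix based on tRNA frequencies alone).
#' @param tol convergence tolerance on max(|d alpha|, |d beta|).
#' @param max_iter maximum iterations.
#' @param reference optional list (parallel to `runs`) of reference
#'   `reading_matrix` objects defining the emissions during estimation.
#' @return a `reuse_params` with attributes `converged` (logical) and
#'   `trace` (data frame of iterates).
#' @export
estimate_reuse <- function(runs, trnas, init = reuse_params(0, 0),
                           tol = 1e-4, max_iter = 20L, reference = NULL) {
  if (inherits(runs, "syn_runs")) runs <- list(runs)
  if (length(runs) == 0L || all(vapply(runs, function(r) length(r$runs), 0L) == 0L)) {
    stop("no runs to estimate reuse from", call. = FALSE)
  }
  fams <- lapply(runs, `[[`, "family")
  fam_trnas <- lapply(fams, function(f) trnas_for_family(trnas, f))
  if (is.null(reference)) {
    reference <- mapply(wobble_rules_reading, fams, fam_trnas,
                        MoreArgs = list(variant = "restricted"),
                        SIMPLIFY = FALSE)
  }
  E_list <- lapply(reference, build_emissions)
  idx_list <- mapply(function(r, f) .runs_to_indices(r$runs, f$codons),
                     runs, fams, SIMPLIFY = FALSE)
  w_list <- lapply(fam_trnas, function(tr) tr$copies / sum(tr$copies))
  cur <- init
  trace <- data.frame(iter = integer(), alpha = numeric(), beta = numeric())
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w_all <- d_all <- wt_all <- numeric(0)
    for (f in seq_along(runs)) {
      if (length(idx_list[[f]]) == 0L) next
      w <- w_list[[f]]
      T <- build_transitions(fam_trnas[[f]], cur)
      pi <- stationary_start(T)
      paths <- .viterbi_batch(E_list[[f]], T, pi, idx_list[[f]])
      from <- unlist(lapply(paths, function(p) p[-length(p)]))
      to <- unlist(lapply(paths, function(p) p[-1L]))
      if (length(from) == 0L) next
      S <- length(w)
      n_from <- tabulate(from, nbins = S)
      n_self <- tabulate(from[from == to], nbins = S)
      ok <- n_from > 0L
      fii <- n_self[ok] / n_from[ok]
      fii <- pmin(fii, 1 - 1e-9)
      d_hat <- (fii - w[ok]) / (1 - fii)
      # delta-method weights: Var(d) ~ f(1-f)/n * (1-w)^2 / (1-f)^4
      v <- pmax(fii * (1 - fii), 1e-9) / n_from[ok] *
        (1 - w[ok])^2 / (1 - fii)^4
      w_all <- c(w_all, w[ok])
      d_all <- c(d_all, d_hat)
      wt_all <- c(wt_all, 1 / v)
    }
    if (length(d_all) < 2L) {
      stop("too few tRNA states with observed transitions to fit reuse parameters",
           call. = FALSE)
    }
    fit <- stats::lm.wfit(cbind(1, w_all), d_all, wt_all)
    new_alpha <- unname(fit$coefficients[1])
    new_beta <- unname(fit$coefficients[2])
    if (is.na(new_beta)) { new_beta <- 0 }  # degenerate: single distinct w
    delta <- max(abs(new_alpha - cur$alpha), abs(new_beta - cur$beta))
    trace <- rbind(trace, data.frame(iter = it, alpha = new_alpha, beta = new_beta))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    cur <- reuse_params(new_alpha, new_beta)
  }
  out <- cur
  attr(out, "converged") <- converged
  attr(out, "trace") <- trace
  out
}
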