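test_that("emission rows spread probability uniformly over read codons", {
  E <- build_emissions(ala_true_reading)
  expect_equal(unname(E[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(rowSums(E)), c(1, 1))
  one <- reading_matrix(ala_family, ala_trnas,
                        rbind(c(0, 0, 0, 1), c(1, 1, 1, 1)))
  E1 <- build_emissions(one)
  expect_equal(unname(E1[1, ]), c(0, 0, 0, 1))
  expect_equal(unname(E1[2, ]), rep(0.25, 4))
})

test_that("transition matrix reduces to abundance rows without reuse", {
  T0 <- build_transitions(ala_trnas, reuse_params(0, 0))
  w <- c(11, 5) / 16
  expect_equal(unname(T0[1, ]), w)
  expect_equal(unname(T0[2, ]), w)
})

test_that("reuse boosts the diagonal, more for rare tRNAs", {
  T1 <- build_transitions(ala_trnas, reuse_params())
  expect_equal(unname(rowSums(T1)), c(1, 1))
  # diagonal exceeds the off-diagonal entry in the same column
  expect_gt(T1[1, 1], T1[2, 1])
  expect_gt(T1[2, 2], T1[1, 2])
  # the rarer tRNA (smaller w) receives the larger absolute boost
  w <- c(11, 5) / 16
  boost <- diag(T1) * 1 - w / (1 + pmax(0, 0.065 - 0.087 * w))  # sanity only
  d <- pmax(0, 0.065 - 0.087 * w)
  expect_gt(d[2], d[1])
  expect_equal(unname(diag(T1)), (w + d) / (1 + d))
  expect_error(build_transitions(trna_set(c("Ala", "Ala"), c("AGC", "UGC"),
                                          c(0, 0))),
               "degenerate")
})

test_that("stationary start is the left unit eigenvector", {
  Tsym <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  expect_equal(unname(stationary_start(Tsym)), c(0.5, 0.5))
  # alpha = beta = 0: identical rows imply stationary = abundance weights
  T0 <- build_transitions(ala_trnas, reuse_params(0, 0))
  expect_equal(unname(stationary_start(T0)), c(11, 5) / 16)
  # definition: pi T = pi
  T1 <- build_transitions(ala_trnas, reuse_params())
  pi1 <- stationary_start(T1)
  expect_equal(drop(pi1 %*% T1), pi1, tolerance = 1e-10)
})

test_that("forward recursion matches the closed form for one state", {
  fam <- toy_family(4)
  tr <- toy_trnas(1)
  rd <- reading_matrix(fam, tr, matrix(1, 1, 4))
  m <- hmm_model(rd)
  run <- rep("GCU", 7)
  expect_equal(forward_log_prob(m, run), 7 * log(1 / 4), tolerance = 1e-12)
})

test_that("forward recursion matches path enumeration for small models", {
  set.seed(21)
  for (S in 1:3) {
    for (k in 2:4) {
      fam <- toy_family(k)
      tr <- toy_trnas(S, copies = sample(1:12, S))
      rd <- random_reading(fam, tr)
      m <- hmm_model(rd, reuse_params())
      for (L in 1:5) {
        idx <- sample(k, L, replace = TRUE)
        got <- forward_log_prob(m, idx)
        want <- forward_oracle(m$E, m$T, m$pi, idx)
        if (is.finite(want)) {
          expect_equal(got, want, tolerance = 1e-12)
        } else {
          expect_identical(got, -Inf)
        }
      }
    }
  }
})

test_that("a codon emitted by no state yields -Inf", {
  rd <- ala_true_reading
  m <- hmm_model(rd)
  m$E[, 4] <- 0  # GCG unreadable
  expect_identical(forward_log_prob(m, c("GCU", "GCG")), -Inf)
})

test_that("forward probabilities over all runs of fixed length sum to one", {
  for (k in 2:4) {
    fam <- toy_family(k)
    tr <- toy_trnas(2, copies = c(3, 9))
    rd <- random_reading(fam, tr, seed = k)
    m <- hmm_model(rd)
    for (n in 1:3) {
      runs <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), n)))
      tot <- sum(exp(vapply(seq_len(nrow(runs)),
                            function(i) forward_log_prob(m, runs[i, ]),
                            numeric(1))))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("total HMM score sums per-run likelihoods, order-invariantly", {
  runs <- structure(list(family = ala_family,
                         runs = list(a = c("GCU", "GCC", "GCA"),
                                     b = c("GCG", "GCG", "GCU"))),
                    class = "syn_runs")
  sc <- score_reading_hmm(ala_true_reading, runs)
  m <- hmm_model(ala_true_reading)
  expect_equal(sc$total_log_prob,
               forward_log_prob(m, runs$runs$a) +
                 forward_log_prob(m, runs$runs$b))
  runs_rev <- runs
  runs_rev$runs <- rev(runs_rev$runs)
  expect_equal(score_reading_hmm(ala_true_reading, runs_rev)$total_log_prob,
               sc$total_log_prob)
  # empty run set scores 0
  empty <- structure(list(family = ala_family, runs = list()),
                     class = "syn_runs")
  expect_equal(score_reading_hmm(ala_true_reading, empty)$total_log_prob, 0)
})

test_that("scores are invariant under consistent codon relabeling", {
  sim <- simulate_corpus(make_sim(n_genes = 60, seed = 9))
  corp <- as_cds_corpus(sim)
  runs <- build_runs(corp, ala_family)
  perm <- c(3, 1, 4, 2)
  fam_p <- structure(list(amino_acid = "A", codons = ala_family$codons[perm]),
                     class = "aa_family")
  runs_p <- runs
  runs_p$family <- fam_p
  space <- enumerate_all_readings(ala_family, ala_trnas, options = NULL)
  sc <- vapply(space$readings, function(r) {
    score_reading_hmm(r, runs)$total_log_prob
  }, numeric(1))
  sc_p <- vapply(space$readings, function(r) {
    r_p <- reading_matrix(fam_p, ala_trnas, r$reads[, perm])
    score_reading_hmm(r_p, runs_p)$total_log_prob
  }, numeric(1))
  expect_equal(sort(sc), sort(sc_p), tolerance = 1e-9)
  expect_equal(sc, sc_p, tolerance = 1e-9)
})

test_that("viterbi decodes forced paths and breaks ties low", {
  m <- hmm_model(ala_true_reading)
  paths <- viterbi_paths(m, list(c("GCU", "GCA", "GCC")))
  expect_equal(paths[[1]], c(1L, 2L, 1L))
  # symmetric model: ties resolve to state 1
  fam <- toy_family(2)
  tr <- toy_trnas(2, copies = c(5, 5))
  rd <- reading_matrix(fam, tr, rbind(c(1, 1), c(1, 1)))
  ms <- hmm_model(rd, reuse_params(0, 0))
  expect_equal(viterbi_paths(ms, list(c("GCU", "GCC")))[[1]], c(1L, 1L))
})

test_that("estimate_reuse with tol = Inf returns the initial parameters", {
  sim <- simulate_corpus(make_sim(n_genes = 40, seed = 3))
  runs <- build_runs(as_cds_corpus(sim), ala_family)
  init <- reuse_params(0.01, -0.02)
  est <- estimate_reuse(runs, ala_trnas, init = init, tol = Inf)
  expect_equal(est$alpha, 0.01)
  expect_equal(est$beta, -0.02)
  expect_true(attr(est, "converged"))
  expect_equal(nrow(attr(est, "trace")), 1L)
})
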