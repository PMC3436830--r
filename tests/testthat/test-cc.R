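make_pairs <- function(X, family = ala_family) {
  k <- length(family$codons)
  dimnames(X) <- list(family$codons, family$codons)
  structure(list(family = family, X = X, n_pairs = sum(X)),
            class = "pair_counts")
}

test_that("expected pair counts follow the independence binomial model", {
  # uniform frequencies over 4 codons, N = 160: every cell expects 10
  counts <- c(GCU = 100, GCC = 100, GCA = 100, GCG = 100)
  pairs <- make_pairs(matrix(10L, 4, 4))
  ev <- expected_pairs(counts, pairs)
  expect_equal(unname(ev$E), matrix(10, 4, 4))
  expect_equal(unname(ev$V), matrix(160 * (1 / 16) * (15 / 16), 4, 4))
  expect_equal(sum(ev$E), pairs$n_pairs)
  # a single used codon concentrates expectation on the diagonal
  counts1 <- c(GCU = 50, GCC = 0, GCA = 0, GCG = 0)
  ev1 <- expected_pairs(counts1, pairs)
  expect_equal(unname(ev1$E[1, 1]), 160)
  expect_equal(sum(ev1$E) - ev1$E[1, 1], 0)
})

test_that("z matrix standardizes cellwise and zeroes void cells", {
  counts <- c(GCU = 100, GCC = 100, GCA = 100, GCG = 100)
  pairs <- make_pairs(matrix(10L, 4, 4))
  zm <- z_matrix(pairs, counts = counts)
  expect_equal(unname(zm$Z), matrix(0, 4, 4))  # X equals E exactly
  X2 <- matrix(10L, 4, 4); X2[1, 1] <- 20L; X2[1, 2] <- 0L  # N stays 160
  zm2 <- z_matrix(make_pairs(X2), counts = counts)
  v <- 160 * (1 / 16) * (15 / 16)
  expect_equal(zm2$Z[1, 1], (20 - 10) / sqrt(v))
  expect_equal(zm2$Z[1, 2], (0 - 10) / sqrt(v))
  # zero-variance cells are masked to 0
  counts0 <- c(GCU = 50, GCC = 50, GCA = 0, GCG = 0)
  zm0 <- z_matrix(pairs, counts = counts0)
  expect_equal(zm0$Z[3, 3], 0)
  expect_false(zm0$mask[3, 3])
})

test_that("z cells on i.i.d. multinomial data are approximately standard normal", {
  set.seed(77)
  p <- c(0.4, 0.3, 0.2, 0.1)
  N <- 10000
  zs <- replicate(60, {
    draws <- sample(4, N + 1, replace = TRUE, prob = p)
    X <- unclass(table(factor(draws[-(N + 1)], levels = 1:4),
                       factor(draws[-1], levels = 1:4)))
    cnt <- setNames(tabulate(draws, 4) * 10, ala_family$codons)
    pairs <- make_pairs(matrix(as.integer(X), 4, 4))
    z_matrix(pairs, counts = cnt)$Z[2, 3]
  })
  expect_lt(abs(mean(zs)), 0.5)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.25)
})

test_that("block score sums signed off-diagonal counts", {
  counts <- c(GCU = 100, GCC = 100, GCA = 100, GCG = 100)
  X <- matrix(10L, 4, 4)
  # one tRNA reading everything: C is all +1, s_obs = all off-diagonal counts
  rd_all <- reading_matrix(ala_family, trna_set("Ala", "AGC", 11),
                           matrix(1, 1, 4))
  sc_all <- score_reading_cc(rd_all, make_pairs(X), counts = counts)
  expect_true(all(sc_all$C == 1))
  expect_true(sc_all$degenerate)
  expect_equal(sc_all$s_obs, sum(X) - sum(diag(X)))
  # X = E: z_total is 0 for every reading
  pl <- plausible_readings(ala_family, ala_trnas)
  for (rd in pl) {
    expect_equal(score_reading_cc(rd, make_pairs(X), counts = counts)$z_total, 0)
  }
})

test_that("z_total is antisymmetric under flipping the sign matrix", {
  counts <- c(GCU = 120, GCC = 80, GCA = 60, GCG = 40)
  set.seed(13)
  X <- matrix(rpois(16, 12), 4, 4)
  pairs <- make_pairs(X)
  rd <- ala_true_reading
  sc <- score_reading_cc(rd, pairs, counts = counts)
  # complementary reading: same-tRNA pairs become different-tRNA pairs
  zm <- z_matrix(pairs, counts = counts)
  off <- row(sc$C) != col(sc$C)
  s_obs_f <- sum(-sc$C[off] * zm$X[off])
  s_exp_f <- sum(-sc$C[off] * zm$E[off])
  z_flip <- (s_obs_f - s_exp_f) / sqrt(sum(zm$V[off]))
  expect_equal(z_flip, -sc$z_total)
})

test_that("adding a constant to off-diagonal cells shifts s_obs by c * sum(C)", {
  counts <- c(GCU = 120, GCC = 80, GCA = 60, GCG = 40)
  set.seed(14)
  X <- matrix(rpois(16, 12), 4, 4)
  rd <- ala_true_reading
  sc1 <- score_reading_cc(rd, make_pairs(X), counts = counts)
  X2 <- X + 5L; diag(X2) <- diag(X)
  sc2 <- score_reading_cc(rd, make_pairs(X2), counts = counts)
  off <- row(X) != col(X)
  expect_equal(sc2$s_obs - sc1$s_obs, 5 * sum(sc1$C[off]))
})

test_that("block recovery: reuse-simulated data favor the true reading", {
  sim <- simulate_corpus(make_sim(n_genes = 400, seed = 23,
                                  reuse = reuse_params(0.3, 0)))
  corp <- as_cds_corpus(sim)
  runs <- build_runs(corp, ala_family)
  pairs <- count_pairs(runs)
  counts <- count_codons(corp)
  pl <- plausible_readings(ala_family, ala_trnas)
  z <- vapply(pl, function(r) {
    score_reading_cc(r, pairs, counts = counts)$z_total
  }, numeric(1))
  expect_equal(reading_id(pl[[which.max(z)]]), reading_id(ala_true_reading))
  # diagonal of Z is positive under reuse
  zm <- z_matrix(pairs, counts = counts)
  expect_gt(mean(diag(zm$Z)), 0)
})
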