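test_that("min-max normalization maps scores onto [0, 1] rank-preservingly", {
  expect_equal(normalize_scores(c(2, 4, 6)), c(0, 0.5, 1))
  s <- c(-3.2, 0.1, 7, 7, 2)
  n <- normalize_scores(s)
  expect_equal(max(n), 1)
  expect_equal(min(n), 0)
  expect_equal(order(n), order(s))
  # invariance under positive affine transforms
  expect_equal(normalize_scores(3 * s + 10), n)
  # degenerate: all equal
  d <- normalize_scores(c(5, 5, 5))
  expect_equal(as.numeric(d), rep(0.5, 3))
  expect_true(attr(d, "degenerate"))
})

test_that("empirical p-values follow (r + 1)/(n + 1) with ties in r", {
  nulls <- seq_len(99)
  expect_equal(empirical_p(100, nulls)$p, 0.01)   # beats all 99
  expect_equal(empirical_p(98.5, nulls)$p, 0.02)  # rank 2
  expect_equal(empirical_p(0, nulls)$p, 1.0)      # below all
  # a tie counts toward r
  expect_equal(empirical_p(99, nulls)$p, 0.02)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("randomize_runs preserves run structure and is seeded", {
  sim <- simulate_corpus(make_sim(n_genes = 80, seed = 2))
  runs <- build_runs(as_cds_corpus(sim), ala_family)
  counts <- count_codons(as_cds_corpus(sim))
  r1 <- randomize_runs(runs, counts, seed = 5)
  r2 <- randomize_runs(runs, counts, seed = 5)
  r3 <- randomize_runs(runs, counts, seed = 6)
  expect_identical(lengths(r1$runs), lengths(runs$runs))
  expect_identical(r1$runs, r2$runs)
  expect_false(identical(r1$runs, r3$runs))
  expect_true(all(unlist(r1$runs) %in% ala_family$codons))
})

test_that("randomized codon frequencies converge to the source frequencies", {
  set.seed(41)
  lens <- rep(50, 2000)  # 1e5 codons
  runs <- structure(list(family = ala_family,
                         runs = lapply(lens, function(L) rep("GCU", L))),
                    class = "syn_runs")
  counts <- c(GCU = 4000, GCC = 3000, GCA = 2000, GCG = 1000)
  rr <- randomize_runs(runs, counts, seed = 8)
  obs <- table(factor(unlist(rr$runs), levels = ala_family$codons))
  chi <- chisq.test(obs, p = counts / sum(counts))
  expect_gt(chi$p.value, 0.001)
})

test_that("skew-normal count randomization is moment-matched and seeded", {
  counts <- c(GCU = 5000, GCC = 2500, GCA = 1500, GCG = 500)
  d1 <- randomize_counts_skewnormal(counts, ala_family, seed = 3)
  d2 <- randomize_counts_skewnormal(counts, ala_family, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0))
  # zero-variance counts: all draws equal the mean
  flat <- c(GCU = 100, GCC = 100, GCA = 100, GCG = 100)
  expect_equal(unname(randomize_counts_skewnormal(flat, ala_family, seed = 1)),
               rep(100, 4))
  # moments of many draws match the source's mean and sd
  set.seed(9)
  draws <- replicate(4000, randomize_counts_skewnormal(counts, ala_family))
  expect_equal(mean(draws), mean(counts), tolerance = 0.05)
  expect_equal(sd(as.numeric(draws)), sd(counts), tolerance = 0.08)
})

test_that("the p-value is uniform on its support under an exchangeable null", {
  set.seed(55)
  n <- 19
  reps <- 2000
  scores <- matrix(rnorm(reps * (n + 1)), reps)
  p <- vapply(seq_len(reps), function(i) {
    empirical_p(scores[i, 1], scores[i, -1])$p
  }, numeric(1))
  tab <- table(factor(round(p * (n + 1)), levels = 1:(n + 1)))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("consensus tally partitions families by agreement pattern", {
  pred <- list(
    f1 = list(hmm = "a", reg = "a", cc = "a"),
    f2 = list(hmm = "a", reg = "a", cc = "b"),
    f3 = list(hmm = "a", reg = "b", cc = "a"),
    f4 = list(hmm = "b", reg = "a", cc = "a"),
    f5 = list(hmm = "a", reg = "b", cc = "c"))
  ct <- consensus_tally(pred)
  expect_equal(unname(ct$counts),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(ct$counts), ct$n_families)
  # identical predictions everywhere: all in the centre
  pred_id <- lapply(1:4, function(i) list(hmm = "x", reg = "x", cc = "x"))
  expect_equal(unname(consensus_tally(pred_id)$counts[1]), 4L)
  # a family missing one method is excluded with a warning
  pred_miss <- c(pred, list(f6 = list(hmm = "a", reg = NULL, cc = "a")))
  expect_warning(ct2 <- consensus_tally(pred_miss), "excluded")
  expect_equal(ct2$n_families, 5L)
})

test_that("consensus centre count matches the analytic random expectation", {
  # independent uniform predictions over m readings: P(all agree) = 1/m^2
  set.seed(66)
  m <- 4
  n_fam <- 60
  reps <- 400
  centre <- replicate(reps, {
    pred <- lapply(seq_len(n_fam), function(i) {
      list(hmm = sample(m, 1), reg = sample(m, 1), cc = sample(m, 1))
    })
    consensus_tally(pred)$counts[["all_three"]]
  })
  expect_equal(mean(centre), n_fam / m^2, tolerance = 0.12)
  # and the tally machinery attaches expected counts + p-values
  pred <- lapply(seq_len(n_fam), function(i) {
    list(hmm = sample(m, 1), reg = sample(m, 1), cc = sample(m, 1))
  })
  nulls <- lapply(1:19, function(b) {
    lapply(seq_len(n_fam), function(i) {
      list(hmm = sample(m, 1), reg = sample(m, 1), cc = sample(m, 1))
    })
  })
  ct <- consensus_tally(pred, nulls)
  expect_length(ct$expected, 5L)
  expect_true(all(ct$p_values >= 1 / 20 & ct$p_values <= 1))
})
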