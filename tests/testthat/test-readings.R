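test_that("enumeration matches the brute-force bitmask oracle", {
  cases <- list(c(n = 1, k = 2), c(n = 2, k = 2), c(n = 2, k = 3),
                c(n = 2, k = 4), c(n = 3, k = 2), c(n = 3, k = 3))
  for (cs in cases) {
    fam <- toy_family(cs["k"])
    tr <- toy_trnas(cs["n"])
    space <- enumerate_all_readings(fam, tr, options = NULL)
    expect_setequal(space$ids, enumerate_oracle_ids(cs["n"], cs["k"]))
  }
  # the two fixed counts
  expect_length(enumerate_all_readings(toy_family(2), toy_trnas(1),
                                       options = NULL)$readings, 1L)
  expect_length(enumerate_all_readings(toy_family(2), toy_trnas(2),
                                       options = NULL)$readings, 7L)
})

test_that("plausible readings are a subset of the full enumeration", {
  space <- enumerate_all_readings(ala_family, ala_trnas)
  pl_ids <- vapply(plausible_readings(ala_family, ala_trnas), reading_id,
                   character(1))
  expect_true(all(pl_ids %in% space$ids))
  expect_equal(sort(space$ids[space$plausible]), sort(pl_ids))
  expect_true(reading_id(ala_true_reading) %in% pl_ids)
})

test_that("plausible readings honor the wobble-option cross product", {
  # lone G-wobble tRNA in a pyrimidine two-codon box reads both codons
  fam2 <- structure(list(amino_acid = "N", codons = c("AAU", "AAC")),
                    class = "aa_family")
  g_trna <- trna_set("Asn", "GUU", 8)
  pl <- plausible_readings(fam2, g_trna)
  expect_length(pl, 1L)
  expect_equal(unname(pl[[1]]$reads[1, ]), c(1L, 1L))

  # a C-wobble tRNA reads only the G-ending codon
  fam_q <- structure(list(amino_acid = "Q", codons = c("CAA", "CAG")),
                     class = "aa_family")
  tr_q <- trna_set(c("Gln", "Gln"), c("UUG", "CUG"), c(9, 1))
  pl_q <- plausible_readings(fam_q, tr_q)
  c_rows <- vapply(pl_q, function(r) paste(r$reads["CUG", ], collapse = ""),
                   character(1))
  expect_true(all(c_rows == "01"))

  # restricted option sets: U-wobble with {A} or {A,G}, G-wobble partner
  # in a 4-box; the {A} choice leaves the G-ending codon uncovered and is
  # dropped, so a single combination survives
  opts <- list(U = list("A", c("A", "G")), G = list(c("C", "U")))
  tr_ug <- trna_set(c("Ala", "Ala"), c("UGC", "GGC"), c(5, 11))
  pl_ug <- plausible_readings(ala_family, tr_ug, opts)
  expect_length(pl_ug, 1L)
  expect_equal(unname(pl_ug[[1]]$reads["UGC", ]), c(0L, 0L, 1L, 1L))
  # widening the option list reinstates the cross-product choices
  opts2 <- list(U = list(c("A", "G"), c("A", "G", "U")), G = list(c("C", "U")))
  expect_length(plausible_readings(ala_family, tr_ug, opts2), 2L)
})

test_that("plausibility infeasibility names the uncovered codons", {
  # a single C-wobble tRNA cannot cover a 4-codon box
  tr_c <- trna_set("Ala", "CGC", 2)
  expect_error(plausible_readings(ala_family, tr_c), "no plausible reading")
})

test_that("wobble-option configs are validated", {
  expect_error(read_wobble_options_list <- local({
    path <- tempfile(fileext = ".yaml")
    writeLines("C:\n  - [G, U]", path)
    read_wobble_options(path)
  }), "cognate")
  path <- tempfile(fileext = ".yaml")
  writeLines("U:\n  - [G]", path)  # lacks the Watson-Crick partner A
  expect_error(read_wobble_options(path), "Watson-Crick")
})

test_that("wobble rules readings follow Crick's pairing sets", {
  wr <- wobble_rules_reading(ala_family, ala_trnas, "original")
  # U-wobble reads {A, G}-ending codons
  expect_equal(unname(wr$reads["UGC", ]), c(0L, 0L, 1L, 1L))
  # A treated as inosine: original reads {A, C, U}-ending codons
  expect_equal(unname(wr$reads["AGC", ]), c(1L, 1L, 1L, 0L))
  # restricted variant drops the I:A pairing
  wr2 <- wobble_rules_reading(ala_family, ala_trnas, "restricted")
  expect_equal(unname(wr2$reads["AGC", ]), c(1L, 1L, 0L, 0L))
})

test_that("wobble rules are idempotent and independent of tRNA order", {
  r1 <- wobble_rules_reading(ala_family, ala_trnas, "original")
  r2 <- wobble_rules_reading(ala_family, ala_trnas, "original")
  expect_true(reading_equal(r1, r2))
  rev_trnas <- ala_trnas[2:1, ]
  class(rev_trnas) <- c("trna_set", "data.frame")
  r3 <- wobble_rules_reading(ala_family, rev_trnas, "original")
  expect_equal(r1$reads["AGC", ], r3$reads["AGC", ])
  expect_equal(r1$reads["UGC", ], r3$reads["UGC", ])
})

test_that("uncovered codons under the rules attach a coverage warning", {
  tr_c <- trna_set("Ala", "CGC", 2)
  expect_warning(r <- wobble_rules_reading(ala_family, tr_c, "original"),
                 "unreadable")
  expect_equal(attr(r, "coverage_warning"), c("GCU", "GCC", "GCA"))
})

test_that("wobble parsimony applies its three passes in order", {
  # every codon with a cognate tRNA: canonical (diagonal) decoding only
  tr4 <- trna_set(rep("Ala", 4), c("AGC", "GGC", "UGC", "CGC"), rep(1, 4))
  wp <- wobble_parsimony_reading(ala_family, tr4)
  expect_equal(unname(rowSums(wp$reads)), rep(1L, 4))
  expect_equal(unname(diag(wp$reads[c("AGC", "GGC", "UGC", "CGC"),
                                    c("GCU", "GCC", "GCA", "GCG")])),
               rep(1L, 4))

  # 4-box with A- and U-wobble tRNAs: A gains the C-ending codon in pass
  # 2 (I:C), U gains the G-ending codon in pass 3 (U:G)
  wp2 <- wobble_parsimony_reading(ala_family, ala_trnas)
  expect_equal(unname(wp2$reads["AGC", ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(wp2$reads["UGC", ]), c(0L, 0L, 1L, 1L))

  expect_error(wobble_parsimony_reading(ala_family, ala_trnas, "prokaryote"),
               "eukaryote")
})

test_that("reading matrices validate coverage", {
  expect_error(reading_matrix(ala_family, ala_trnas,
                              rbind(c(0, 0, 0, 0), c(1, 1, 1, 1))),
               "no codon")
  expect_error(reading_matrix(ala_family, ala_trnas,
                              rbind(c(1, 1, 0, 0), c(0, 0, 1, 0))),
               "no tRNA")
})
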