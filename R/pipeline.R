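# End-to-end prediction pipeline: per non-trivial family, enumerate
# readings, score by each method, normalize over the solution space,
# randomize, and attach empirical p-values.

.method_scores <- function(method, readings, runs, counts, pairs, reuse,
                           shared_model = NULL, zmat = NULL) {
  switch(method,
    hmm = vapply(readings, function(r) {
      score_reading_hmm(r, runs, reuse, model = shared_model)$total_log_prob
    }, numeric(1)),
    reg = vapply(readings, function(r) {
      score_reading_reg(r, counts)$r_squared
    }, numeric(1)),
    cc = vapply(readings, function(r) {
      score_reading_cc(r, pairs, zmat = zmat)$z_total
    }, numeric(1)),
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

.null_best_scores <- function(method, plausible, runs, counts, pairs, reuse,
                              n_rand, shared_model) {
  family <- plausible[[1]]$family
  vapply(seq_len(n_rand), function(b) {
    if (method == "reg") {
      rc <- randomize_counts_skewnormal(counts, family)
      max(vapply(plausible, function(r) score_reading_reg(r, rc)$r_squared,
                 numeric(1)), na.rm = TRUE)
    } else {
      rr <- randomize_runs(runs, counts)
      if (method == "hmm") {
        max(vapply(plausible, function(r) {
          score_reading_hmm(r, rr, reuse, model = shared_model)$total_log_prob
        }, numeric(1)))
      } else {
        rp <- count_pairs(rr)
        zm <- z_matrix(rp, counts = counts)
        max(vapply(plausible, function(r) {
          score_reading_cc(r, rp, zmat = zm)$z_total
        }, numeric(1)))
      }
    }
  }, numeric(1))
}

#' Predict codon readings for every family of a corpus
#'
#' For each amino-acid family (split into codon boxes) present in the
#' tRNA set: enumerate the plausible readings, score them with the
#' requested methods, normalize scores over the solution space (the full
#' enumeration when it is small enough, otherwise the plausible subset),
#' and compute Monte-Carlo empirical p-values of the best plausible
#' score against randomized corpora. Families whose reading is forced
#' (single codon, or a single plausible reading) are reported as
#' trivial without scoring.
#'
#' @param corpus a `cds_corpus` (from [load_cds()] or
#'   [as_cds_corpus()]).
#' @param trnas a `trna_set`.
#' @param methods subset of `c("hmm", "reg", "cc")`.
#' @param options wobble-option configuration.
#' @param reuse `reuse_params` for the HMM.
#' @param n_rand randomized replicates per method and family
#'   (default 99).
#' @param seed integer seed controlling all randomization.
#' @param max_enumerate largest full solution space to enumerate for
#'   score normalization; larger families normalize over the plausible
#'   subset only.
#' @return an object of class `wobblescan_predictions`: list with
#'   `table` (one row per family x method: `family`, `method`,
#'   `best_reading`, `score`, `s_n`, `rank_in_space`, `space_size`,
#'   `p_value`, `n_rand`, `seed`), `trivial` (data frame of trivial
#'   families), `details` (per-family scored spaces), and `seed`.
#' @export
predict_readings <- function(corpus, trnas, methods = c("hmm", "reg", "cc"),
                             options = default_wobble_options(),
                             reuse = reuse_params(), n_rand = 99L,
                             seed = 1L, max_enumerate = 4096) {
  methods <- match.arg(methods, c("hmm", "reg", "cc"), several.ok = TRUE)
  stopifnot(inherits(trnas, "trna_set"))
  code <- if (inherits(corpus, "cds_corpus")) corpus$code else genetic_code(1)
  set.seed(seed)
  counts <- count_codons(corpus)
  rows <- list()
  trivial <- list()
  details <- list()
  for (aa in sort(unique(trnas$amino_acid))) {
    fam <- tryCatch(family_of(code, aa), error = function(e) NULL)
    if (is.null(fam)) {
      warning(sprintf("amino acid %s not in genetic code; skipped", aa),
              call. = FALSE)
      next
    }
    for (box in family_boxes(fam)) {
      key <- if (!is.null(box$box)) paste0(aa, "/", box$box, "N") else aa
      fam_trnas <- trnas_for_family(trnas, box)
      if (nrow(fam_trnas) == 0L) {
        warning(sprintf("no tRNAs for family %s; skipped", key), call. = FALSE)
        next
      }
      if (length(box$codons) == 1L) {
        trivial[[key]] <- data.frame(family = key, reason = "single_codon",
                                     n_trnas = nrow(fam_trnas))
        next
      }
      plausible <- tryCatch(plausible_readings(box, fam_trnas, options),
                            error = function(e) {
                              warning(sprintf("family %s: %s", key,
                                              conditionMessage(e)), call. = FALSE)
                              NULL
                            })
      if (is.null(plausible)) next
      if (length(plausible) == 1L) {
        trivial[[key]] <- data.frame(family = key, reason = "single_reading",
                                     n_trnas = nrow(fam_trnas))
        next
      }
      runs <- build_runs(corpus, box)
      pairs <- count_pairs(runs)
      fam_cnt <- family_counts(counts, box)
      if (sum(fam_cnt) == 0) {
        warning(sprintf("family %s absent from corpus; skipped", key),
                call. = FALSE)
        next
      }
      space_n <- (2^length(box$codons) - 1)^nrow(fam_trnas)
      use_full <- space_n <= max_enumerate
      space <- if (use_full) {
        enumerate_all_readings(box, fam_trnas, options = options)
      } else {
        list(readings = plausible,
             ids = vapply(plausible, reading_id, character(1)),
             plausible = rep(TRUE, length(plausible)))
      }
      shared_model <- hmm_model(plausible[[1]], reuse)
      zmat <- z_matrix(pairs, counts = counts)
      fam_detail <- list(family = key, space_full = use_full,
                         ids = space$ids, plausible = space$plausible)
      for (method in methods) {
        sc <- .method_scores(method, space$readings, runs, fam_cnt, pairs,
                             reuse, shared_model, zmat)
        if (all(is.na(sc))) next
        s_n <- normalize_scores(sc)
        pl_idx <- which(space$plausible)
        best_pl <- pl_idx[which.max(sc[pl_idx])]
        rank_in_space <- sum(sc >= sc[best_pl], na.rm = TRUE)
        nulls <- .null_best_scores(method,
                                   space$readings[pl_idx], runs, fam_cnt,
                                   pairs, reuse, n_rand, shared_model)
        ep <- empirical_p(sc[best_pl], nulls)
        rows[[paste(key, method)]] <- data.frame(
          family = key, method = method,
          best_reading = space$ids[best_pl],
          score = sc[best_pl], s_n = s_n[best_pl],
          rank_in_space = rank_in_space,
          space_size = length(space$readings),
          p_value = ep$p, n_rand = ep$n, seed = seed,
          stringsAsFactors = FALSE)
        fam_detail[[method]] <- list(scores = sc, s_n = s_n,
                                     best = space$ids[best_pl],
                                     best_reading = space$readings[[best_pl]],
                                     p = ep$p, null_scores = nulls)
      }
      details[[key]] <- fam_detail
    }
  }
  structure(list(
    table = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(),
    trivial = if (length(trivial)) do.call(rbind, c(trivial, make.row.names = FALSE))
              else data.frame(),
    details = details, seed = seed),
    class = "wobblescan_predictions")
}

#' @export
print.wobblescan_predictions <- function(x, ...) {
  cat(sprintf("wobblescan predictions (%d scored family-method rows, %d trivial families)\n",
              nrow(x$table), nrow(x$trivial)))
  if (nrow(x$table)) {
    print(x$table[, c("family", "method", "best_reading", "score", "s_n",
                      "p_value")], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Baseline reading assignments per family
#'
#' Emits the wobble-rules reading (chosen variant) and, in eukaryote
#' mode, the wobble-parsimony reading for every family of the tRNA set.
#'
#' @param trnas a `trna_set`.
#' @param code a `genetic_code`.
#' @param variant wobble-rules variant, `"original"` or `"restricted"`.
#' @param mode `"eukaryote"` or `"prokaryote"`; parsimony is refused in
#'   prokaryote mode.
#' @param parsimony include the wobble-parsimony baseline (default TRUE;
#'   an error in prokaryote mode).
#' @return data frame with columns `family`, `anticodon`, `method`,
#'   `reads` (codon set string), plus attribute `readings` (named list
#'   of `reading_matrix`).
#' @export
baseline_readings <- function(trnas, code = genetic_code(1),
                              variant = c("original", "restricted"),
                              mode = c("eukaryote", "prokaryote"),
                              parsimony = TRUE) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  if (parsimony && mode == "prokaryote") {
    stop("wobble parsimony is only applicable for eukaryotes", call. = FALSE)
  }
  rows <- list()
  readings <- list()
  for (aa in sort(unique(trnas$amino_acid))) {
    fam <- tryCatch(family_of(code, aa), error = function(e) NULL)
    if (is.null(fam)) next
    for (box in family_boxes(fam)) {
      key <- if (!is.null(box$box)) paste0(aa, "/", box$box, "N") else aa
      fam_trnas <- trnas_for_family(trnas, box)
      if (nrow(fam_trnas) == 0L) next
      baselines <- list(rules = suppressWarnings(
        wobble_rules_reading(box, fam_trnas, variant)))
      if (parsimony) {
        baselines$parsimony <- suppressWarnings(
          wobble_parsimony_reading(box, fam_trnas, mode))
      }
      for (m in names(baselines)) {
        r <- baselines[[m]]
        readings[[paste(key, m, sep = ":")]] <- r
        for (i in seq_len(nrow(fam_trnas))) {
          rows[[length(rows) + 1L]] <- data.frame(
            family = key, anticodon = fam_trnas$anticodon[i],
            method = if (m == "rules") paste0("rules_", variant) else m,
            reads = paste(box$codons[r$reads[i, ] == 1L], collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  attr(out, "readings") <- readings
  out
}

#' Write a prediction table as TSV
#'
#' @param predictions a `wobblescan_predictions`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
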