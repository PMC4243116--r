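test_that("candidate enumeration matches hand counts on a toy set", {
  ss <- toy_seqs()  # two copies of ACACA
  cand <- enumerate_candidates(ss, 3, 3, 2)
  expect_setequal(cand$pattern, c("ACA", "CAC"))
  expect_equal(cand$support, c(2L, 2L))
  # ACA occurs twice per sequence (overlapping)
  expect_equal(cand$occ_count[cand$pattern == "ACA"], 4L)
  expect_warning(out <- enumerate_candidates(ss, 3, 3, 3), "min_occurrence")
  expect_equal(nrow(out), 0L)
})

test_that("enumeration equals the brute-force window-hash oracle", {
  fam <- generate_family(synthetic_spec(n_sequences = 20, length = 50,
                                        motifs = data.frame(
                                          name = "m", consensus = "WKDGHNV",
                                          site = 10L, mutation_rate = 0.1),
                                        groups = list(list(motifs = "m",
                                                           p = 0.8)),
                                        seed = 21))
  ss <- fam$seqs
  cand <- enumerate_candidates(ss, 5, 8, 3)
  oracle <- oracle_enumerate(ss$residues, ss$id, 5, 8, 3)
  expect_equal(sort(cand$pattern), sort(oracle$pattern))
  m <- match(cand$pattern, oracle$pattern)
  expect_equal(cand$support, oracle$support[m])
  expect_equal(cand$occ_count, oracle$occ_count[m])
})

test_that("every recorded occurrence verifies by substring equality", {
  fam <- generate_family(synthetic_spec(n_sequences = 30, seed = 9))
  cand <- enumerate_candidates(fam$seqs, 5, 10, 15)
  occs <- attr(cand, "occurrences")
  for (p in sample(cand$pattern, min(20, nrow(cand)))) {
    o <- occs[[p]]
    for (r in seq_len(nrow(o))) {
      s <- fam$seqs$residues[match(o$seq[r], fam$seqs$id)]
      expect_identical(substr(s, o$start[r], o$start[r] + nchar(p) - 1L), p)
    }
  }
})

test_that("significance is the standard residual against the background", {
  # single-letter background: observed equals expected, z = 0
  ss <- sequence_set(c("AAAA", "AAAA"), c("x", "y"))
  expect_equal(significance_score("AA", ss), 0)
  # absent pattern: z = -sqrt(E)
  ss2 <- sequence_set(c("ACACAC", "AGAGAG"), c("x", "y"))
  E <- 10 * prod(ss2$freq[c("C", "G")])  # 10 windows of length 2
  expect_equal(significance_score("CG", ss2), (0 - E) / sqrt(E))
  # direct recompute on a generated set
  fam <- generate_family(synthetic_spec(n_sequences = 10, seed = 2))
  p <- "WKDGH"
  O <- sum(vapply(fam$seqs$residues, function(s) {
    hits <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
    sum(hits > 0)
  }, numeric(1)))
  W_n <- sum(nchar(fam$seqs$residues) - nchar(p) + 1)
  E <- W_n * prod(fam$seqs$freq[strsplit(p, "")[[1]]])
  expect_equal(significance_score(p, fam$seqs), (O - E) / sqrt(E))
})

test_that("delta-closed pruning applies the support-fraction rule", {
  df <- data.frame(pattern = c("ACD", "ACDE"), length = c(3L, 4L),
                   support = c(10L, 9L), occ_count = c(10L, 9L),
                   stringsAsFactors = FALSE)
  attr(df, "occurrences") <- list(ACD = NULL, ACDE = NULL)
  out <- delta_closed_prune(df, 0.9)
  expect_equal(out$pattern, "ACDE")  # 9 >= 0.9 * 10 prunes the substring
  out2 <- delta_closed_prune(df, 0.95)
  expect_setequal(out2$pattern, c("ACD", "ACDE"))  # 9 < 9.5 keeps both
})

test_that("pruning matches the all-pairs oracle and is idempotent", {
  fam <- generate_family(synthetic_spec(n_sequences = 40, seed = 13))
  cand <- enumerate_candidates(fam$seqs, 5, 12, 10)
  out <- delta_closed_prune(cand, 0.9)
  expect_equal(sort(out$pattern), oracle_prune(cand, 0.9))
  again <- delta_closed_prune(out, 0.9)
  expect_equal(sort(again$pattern), sort(out$pattern))
})

test_that("raising min_occurrence never adds patterns", {
  fam <- generate_family(synthetic_spec(n_sequences = 40, seed = 17))
  lo <- enumerate_candidates(fam$seqs, 5, 10, 10)
  hi <- suppressWarnings(enumerate_candidates(fam$seqs, 5, 10, 25))
  expect_true(all(hi$pattern %in% lo$pattern))
})

test_that("discovery keeps planted motifs and drops random noise", {
  # a planted motif present in 25/30 sequences survives discovery
  fam <- generate_family(synthetic_spec(
    n_sequences = 30, length = 80,
    motifs = data.frame(name = "m", consensus = "WKDGHNVFT", site = 30L,
                        mutation_rate = 0),
    groups = list(list(motifs = "m", p = 25 / 30)), seed = 4))
  ps <- discover_patterns(fam$seqs, min_occurrence = 20)
  expect_true(any(grepl("WKDGHNVFT", ps$pattern, fixed = TRUE) |
                    vapply(ps$pattern, grepl, logical(1),
                           x = "WKDGHNVFT", fixed = TRUE)))
  # pure i.i.d. sequences with a high support floor yield nothing
  bg <- generate_family(synthetic_spec(
    n_sequences = 30, length = 80,
    motifs = data.frame(name = "m", consensus = "WKDGHNVFT", site = 30L,
                        mutation_rate = 0),
    groups = list(list(motifs = "m", p = 0)), seed = 8))
  w <- testthat::capture_warnings(
    none <- discover_patterns(bg$seqs, min_occurrence = 20))
  expect_true(any(grepl("no", w)))
  expect_equal(nrow(none), 0L)
})

test_that("identical sequences give the motif maximal support", {
  ss <- sequence_set(rep("MAAGGRLKAAMV", 30), paste0("s", 1:30))
  ps <- discover_patterns(ss, min_len = 5, max_len = 8, min_occurrence = 20)
  expect_true(all(ps$support == 30))
  expect_true(any(grepl("GGRLK", ps$pattern, fixed = TRUE)))
})
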