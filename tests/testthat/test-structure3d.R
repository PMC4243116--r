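write_tmp_pdb <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("a minimal hand-written PDB parses to residues and coordinates", {
  s <- read_structure(write_tmp_pdb(tiny_pdb_lines()))
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$chains[["A"]], "MQI")
  expect_equal(s$atoms$x, c(0, 3.8, 7.6))
})

test_that("altloc C-alphas keep the highest occupancy; hetero excluded", {
  lines <- c(
    "ATOM      1  CA AMET A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BMET A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLN A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    4  CA  HOH A 101       5.000   5.000   5.000  1.00  0.00           C",
    "END")
  s <- read_structure(write_tmp_pdb(lines))
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[1], 9.0)  # occupancy 0.60 wins
  expect_error(read_structure(write_tmp_pdb(c("END"))), "")
})

test_that("residue count matches a CA line-grep oracle on a synthetic file", {
  fam <- generate_family(synthetic_spec(n_sequences = 10, seed = 2))
  sm <- generate_structure_for(fam$truth, fam$seqs, "syn001", "dispersed")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sm, f)
  n_ca <- sum(grepl("^ATOM .* CA ", readLines(f)))
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), n_ca)
  expect_equal(s$chains[["A"]], fam$seqs$residues[1])
})

test_that("APC mapping finds exact, wildcard and partial matches", {
  lines <- tiny_pdb_lines()
  fam <- generate_family(synthetic_spec(n_sequences = 5, seed = 3))
  sm <- generate_structure_for(fam$truth, fam$seqs, "syn002", "dispersed")
  chain <- sm$chains[["A"]]
  # exact prefix match
  apc1 <- structure(list(id = "X", patterns = substr(chain, 1, 6),
                         occurrences = list(), consensus = substr(chain, 1, 6)),
                    class = "aligned_pattern_cluster")
  r <- map_apc_to_structure(apc1, sm)
  expect_equal(r$start, 1L); expect_equal(r$end, 6L)
  # wildcard match
  pat <- paste0(substr(chain, 10, 11), "*", substr(chain, 13, 15))
  apc2 <- structure(list(id = "W", patterns = character(0),
                         occurrences = list(), consensus = pat),
                    class = "aligned_pattern_cluster")
  r2 <- map_apc_to_structure(apc2, sm)
  expect_true(any(r2$start <= 10 & r2$end >= 15))
  # partial: pattern whose tail is absent from the chain
  bogus <- paste0(substr(chain, 20, 26), "WWWWWW")
  apc3 <- structure(list(id = "P", patterns = bogus,
                         occurrences = list(), consensus = bogus),
                    class = "aligned_pattern_cluster")
  r3 <- map_apc_to_structure(apc3, sm, min_partial = 5)
  expect_true(any(r3$start == 20))
  # unmappable APC warns and returns no regions
  apc4 <- structure(list(id = "N", patterns = "WWWWWWWWWW",
                         occurrences = list(), consensus = "WWWWWWWWWW"),
                    class = "aligned_pattern_cluster")
  expect_warning(r4 <- map_apc_to_structure(apc4, sm), "unmapped")
  expect_equal(nrow(r4), 0L)
})

test_that("centroids and centroid distances follow the closed forms", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       2.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- read_structure(write_tmp_pdb(lines))
  expect_equal(unname(region_centroid(s, "A", 1, 2)), c(1, 0, 0))
  expect_equal(unname(region_centroid(s, "A", 2, 2)), c(2, 0, 0))
  # 3-4-5 triangle
  expect_equal(average_apc_distance(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  # coincident centroids give zero
  expect_equal(average_apc_distance(rbind(c(1, 1, 1), c(1, 1, 1))), 0)
  expect_error(average_apc_distance(rbind(c(0, 0, 0))), ">= 2")
  # random centroids vs naive double loop
  set.seed(9)
  cent <- matrix(stats::rnorm(15), 5)
  acc <- c()
  for (i in 1:4) for (j in (i + 1):5)
    acc <- c(acc, sqrt(sum((cent[i, ] - cent[j, ])^2)))
  expect_equal(average_apc_distance(cent), mean(acc))
})

test_that("average pairwise CA distance matches the hand sum and naive loop", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   3       2.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- read_structure(write_tmp_pdb(lines))
  expect_equal(average_pairwise_ca_distance(s), 4 / 3)
  # O(n^2) implementation matches a naive double loop on a bigger trace
  fam <- generate_family(synthetic_spec(n_sequences = 5, seed = 4))
  sm <- generate_structure_for(fam$truth, fam$seqs, "syn003", "colocated")
  xyz <- as.matrix(sm$atoms[, c("x", "y", "z")])
  acc <- 0; cnt <- 0
  for (i in seq_len(nrow(xyz) - 1)) for (j in seq(i + 1, nrow(xyz))) {
    acc <- acc + sqrt(sum((xyz[i, ] - xyz[j, ])^2)); cnt <- cnt + 1
  }
  expect_equal(average_pairwise_ca_distance(sm), acc / cnt, tolerance = 1e-9)
})

test_that("distance summaries are invariant under rigid motion", {
  fam <- generate_family(synthetic_spec(n_sequences = 5, seed = 8))
  sm <- generate_structure_for(fam$truth, fam$seqs, "syn001", "colocated")
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(sm$atoms[, c("x", "y", "z")])
  moved <- sm
  moved$atoms[, c("x", "y", "z")] <- xyz %*% t(R) +
    matrix(c(10, -5, 3), nrow(xyz), 3, byrow = TRUE)
  expect_equal(average_pairwise_ca_distance(moved),
               average_pairwise_ca_distance(sm), tolerance = 1e-9)
  cent <- matrix(stats::rnorm(9), 3)
  cent_moved <- cent %*% t(R) + matrix(c(10, -5, 3), 3, 3, byrow = TRUE)
  expect_equal(average_apc_distance(cent_moved), average_apc_distance(cent),
               tolerance = 1e-9)
})
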