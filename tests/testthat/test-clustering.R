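block_W <- function(sizes, intra = 1, inter = 0) {
  n <- sum(sizes)
  W <- matrix(inter, n, n)
  off <- 0
  for (s in sizes) {
    W[(off + 1):(off + s), (off + 1):(off + s)] <- intra
    off <- off + s
  }
  diag(W) <- 0
  dimnames(W) <- list(paste0("v", 1:n), paste0("v", 1:n))
  W
}

test_that("degree matrix is the diagonal of row sums", {
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(degree_matrix(W), diag(c(1, 1)))
  expect_equal(degree_matrix(matrix(0, 3, 3)), diag(0, 3))
  set.seed(1)
  W <- random_W(6, c(0.1, 0.4, 0.9))
  expect_equal(diag(degree_matrix(W)), rowSums(W))
})

test_that("random-walk Laplacian has the 2-node closed form", {
  W <- matrix(c(0, 1, 1, 0), 2)
  L <- laplacian_rw(W)
  expect_equal(L, matrix(c(1, -1, -1, 1), 2))
  expect_equal(sort(eigen(L, only.values = TRUE)$values), c(0, 2))
  expect_error(laplacian_rw(block_W(c(2, 1), inter = 0)), "isolate")
})

test_that("L_rw eigenvalues match an independent symmetric-Laplacian solver", {
  set.seed(11)
  checked <- 0
  while (checked < 40) {
    n <- sample(3:6, 1)
    W <- random_W(n, c(0.2, 0.5, 1.0))
    if (any(rowSums(W) == 0)) next
    ours <- sort(Re(eigen(laplacian_rw(W), only.values = TRUE)$values))
    expect_equal(ours, oracle_lrw_eigenvalues(W), tolerance = 1e-8)
    expect_true(all(ours > -1e-8 & ours < 2 + 1e-8))
    checked <- checked + 1
  }
})

test_that("zero-eigenvalue multiplicity equals the component count", {
  for (c_count in 1:4) {
    W <- block_W(rep(3, c_count), intra = 0.7, inter = 0)
    # keep components connected but the graph disconnected
    ev <- sort(Re(eigen(laplacian_rw(W), only.values = TRUE)$values))
    expect_equal(sum(abs(ev) < 1e-8), c_count)
  }
})

test_that("eigengap picks the count before the largest gap", {
  expect_equal(eigengap_k(c(0, 0.01, 1.2, 1.3)), 2L)
  expect_equal(eigengap_k(c(0, 2)), 1L)
  expect_warning(k <- eigengap_k(c(0, 1, 2, 3)), "equal")
  expect_equal(k, 1L)
  # two disconnected 3-cliques: eigenvalues {0,0,...} force k = 2
  W <- block_W(c(3, 3))
  ev <- sort(Re(eigen(laplacian_rw(W), only.values = TRUE)$values))
  expect_equal(eigengap_k(ev), 2L)
})

test_that("spectral clustering recovers disconnected cliques exactly", {
  W <- block_W(c(3, 3))
  res <- spectral_cluster(W)
  expect_equal(res$k, 2L)
  expect_equal(unname(res$assignment), c(1, 1, 1, 2, 2, 2))
  expect_lt(abs(res$eigenvalues[1]), 1e-8)
  # duplicated-coverage groups (J=1 within, 0 across) are recovered
  W2 <- block_W(c(4, 2))
  res2 <- spectral_cluster(W2)
  expect_equal(unname(res2$assignment), c(1, 1, 1, 1, 2, 2))
})

test_that("isolated vertices become singleton clusters", {
  W <- block_W(c(3, 1), intra = 0.8, inter = 0)  # v4 isolated
  res <- spectral_cluster(W)
  expect_equal(res$k, 2L)
  expect_equal(unname(res$assignment[4]), 2)
  expect_true(is.na(res$avg_embedding_distance["2"]))
})

test_that("planted 2-block partition matches the exhaustive min-ncut", {
  set.seed(5)
  for (rep in 1:3) {
    W <- block_W(c(5, 5), intra = 0.9, inter = 0.05)
    noise <- matrix(stats::runif(100, -0.05, 0.05), 10)
    noise <- (noise + t(noise)) / 2
    W <- pmin(pmax(W + noise, 0), 1); diag(W) <- 0
    dimnames(W) <- list(paste0("v", 1:10), paste0("v", 1:10))
    res <- spectral_cluster(W, k = 2)
    oracle <- oracle_min_ncut(W)
    side <- unname(res$assignment) == res$assignment[[oracle$side[1]]]
    expect_setequal(which(side), oracle$side)
  }
})

test_that("best-cluster selection minimizes mean embedding distance", {
  W <- block_W(c(3, 3), intra = 1, inter = 0)
  res <- spectral_cluster(W)
  d <- res$avg_embedding_distance
  expect_equal(select_best_cluster(res), as.integer(names(which.min(d))))
  # recompute with a naive all-pairs loop
  for (l in names(d)) {
    members <- names(res$assignment)[res$assignment == as.integer(l)]
    rows <- res$embedding[members, , drop = FALSE]
    acc <- c()
    for (i in seq_len(nrow(rows) - 1))
      for (j in seq(i + 1, nrow(rows)))
        acc <- c(acc, sqrt(sum((rows[i, ] - rows[j, ])^2)))
    expect_equal(unname(d[[l]]), mean(acc))
  }
  # all-singleton case errors
  W0 <- matrix(0, 3, 3); dimnames(W0) <- list(letters[1:3], letters[1:3])
  res0 <- spectral_cluster(W0)
  expect_error(select_best_cluster(res0), "no connected cluster|no embedding")
})

test_that("k-medoids separates disjoint components and picks max-score medoids", {
  W <- block_W(c(3, 4), intra = 0.6, inter = 0)
  res <- kmedoids_cluster(W, k = 2)
  expect_equal(length(unique(res$assignment[1:3])), 1L)
  expect_equal(length(unique(res$assignment[4:7])), 1L)
  expect_false(res$assignment[1] == res$assignment[4])
  # medoid of {a,b,c} with J(a,b)=.9, J(a,c)=.8, J(b,c)=.2 is a
  W3 <- matrix(c(0, .9, .8, .9, 0, .2, .8, .2, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res3 <- kmedoids_cluster(W3, k = 1)
  expect_equal(attr(res3, "medoids"), "a")
})

test_that("k-medoids objective matches exhaustive medoid enumeration", {
  set.seed(17)
  tried <- 0
  while (tried < 5) {
    W <- random_W(8, c(0.1, 0.3, 0.6, 0.9))
    if (any(rowSums(W) == 0)) next
    if (max(graph_comp_count(W)) > 1) next
    res <- kmedoids_cluster(W, k = 2)
    expect_equal(res$objective, oracle_kmedoids2(W), tolerance = 1e-9)
    tried <- tried + 1
  }
})

test_that("MST clustering follows the hand-traced cuts and tie-breaks", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 0.9
  W["a", "c"] <- W["c", "a"] <- 0.8
  W["b", "c"] <- W["c", "b"] <- 0.2
  res <- mst_hierarchical_cluster(W, k = 2)
  expect_equal(unname(res$assignment[c("a", "b")]), c(1, 1))
  expect_equal(unname(res$assignment["c"]), 2)
  # equal-weight chain: lexicographically smallest edge is cut first
  Wc <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  Wc["a", "b"] <- Wc["b", "a"] <- 0.5
  Wc["b", "c"] <- Wc["c", "b"] <- 0.5
  resc <- mst_hierarchical_cluster(Wc, k = 2)
  expect_equal(unname(resc$assignment["a"]) == unname(resc$assignment["b"]),
               FALSE)
  expect_error(mst_hierarchical_cluster(Wc, k = 5), "achievable|k")
})

test_that("Prim forest weight equals exhaustive spanning-tree enumeration", {
  set.seed(23)
  tried <- 0
  while (tried < 4) {
    W <- random_W(6, c(0.2, 0.5, 1.0))
    if (any(rowSums(W) == 0)) next
    if (max(graph_comp_count(W)) > 1) next
    res <- mst_hierarchical_cluster(W, k = 1)
    expect_equal(sum(attr(res, "tree_edges")$weight), oracle_mst_weight(W),
                 tolerance = 1e-12)
    tried <- tried + 1
  }
})

test_that("all three algorithms are permutation-equivariant", {
  set.seed(41)
  W <- block_W(c(4, 3), intra = 0.9, inter = 0.05)
  noise <- matrix(stats::runif(49, 0, 0.03), 7)
  W <- W + (noise + t(noise)) / 2; diag(W) <- 0
  dimnames(W) <- list(paste0("v", 1:7), paste0("v", 1:7))
  perm <- sample(7)
  Wp <- W[perm, perm]
  same_partition <- function(a, b) {
    # compare partitions as label-invariant co-membership
    n <- length(a)
    ca <- outer(a, a, "=="); cb <- outer(b, b, "==")
    identical(ca, cb)
  }
  for (fit in list(
    function(w) spectral_cluster(w, k = 2)$assignment,
    function(w) kmedoids_cluster(w, k = 2)$assignment,
    function(w) mst_hierarchical_cluster(w, k = 2)$assignment)) {
    a <- fit(W)
    b <- fit(Wp)
    expect_true(same_partition(unname(a[paste0("v", 1:7)]),
                               unname(b[paste0("v", 1:7)])))
  }
})

test_that("spectral and k-medoids agree on separable block graphs", {
  for (sizes in list(c(3, 3), c(4, 2), c(5, 3, 2))) {
    W <- block_W(sizes, intra = 0.8, inter = 0)
    a <- spectral_cluster(W)$assignment
    b <- kmedoids_cluster(W, k = length(sizes))$assignment
    ca <- outer(a, a, "=="); cb <- outer(b, b, "==")
    expect_identical(unname(ca), unname(cb))
  }
})
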