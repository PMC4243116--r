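# Independent oracles used to cross-check the implementation. These are
# deliberately naive (hash tables, exhaustive enumeration, brute-force
# loops) and share no code with the package internals.

# Brute-force window counting: every substring of every admissible length,
# tallied in an environment keyed by the string.
oracle_enumerate <- function(residues, ids, min_len, max_len, min_occ) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(residues)) {
    s <- residues[i]
    n <- nchar(s)
    for (L in min_len:min(max_len, n)) {
      for (st in 1:(n - L + 1)) {
        w <- substr(s, st, st + L - 1)
        rec <- if (exists(w, env)) get(w, env) else
          list(seqs = character(), count = 0L)
        rec$seqs <- union(rec$seqs, ids[i])
        rec$count <- rec$count + 1L
        assign(w, rec, env)
      }
    }
  }
  pats <- ls(env)
  supp <- vapply(pats, function(p) length(get(p, env)$seqs), integer(1))
  cnt <- vapply(pats, function(p) get(p, env)$count, integer(1))
  keep <- supp >= min_occ
  data.frame(pattern = pats[keep], support = unname(supp[keep]),
             occ_count = unname(cnt[keep]),
             stringsAsFactors = FALSE)[order(pats[keep]), ]
}

# All-pairs delta-closed pruning: p pruned iff a retained strict
# super-pattern keeps delta of its support; longest first.
oracle_prune <- function(df, delta) {
  ord <- order(-df$length, df$pattern)
  df <- df[ord, ]
  retained <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    pruned <- FALSE
    for (j in seq_len(nrow(df))) {
      if (!retained[j]) next
      if (nchar(df$pattern[j]) <= nchar(df$pattern[i])) next
      if (grepl(df$pattern[i], df$pattern[j], fixed = TRUE) &&
          df$support[j] >= delta * df$support[i]) { pruned <- TRUE; break }
    }
    retained[i] <- !pruned
  }
  sort(df$pattern[retained])
}

# Exhaustive global alignment score by recursion over all alignments.
oracle_align_score <- function(p, q, gap = -0.5) {
  a <- strsplit(p, "")[[1]]; b <- strsplit(q, "")[[1]]
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, (a[i] == b[j]) + rec(i + 1, j + 1))
    if (i <= length(a)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(b)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Eigenvalues of L_rw via the symmetric normalized Laplacian
# L_sym = I - D^-1/2 W D^-1/2, which is similar to L_rw.
oracle_lrw_eigenvalues <- function(W) {
  d <- rowSums(W)
  Dm <- diag(1 / sqrt(d))
  Ls <- diag(nrow(W)) - Dm %*% W %*% Dm
  sort(eigen((Ls + t(Ls)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# Maximum spanning tree weight by enumerating all (n-1)-edge subsets.
oracle_mst_weight <- function(W) {
  n <- nrow(W)
  edges <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(edges)
  best <- -Inf
  for (sel in utils::combn(m, n - 1, simplify = FALSE)) {
    A <- matrix(0, n, n)
    A[edges[sel, , drop = FALSE]] <- 1
    A <- A + t(A)
    # connectivity check by BFS
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(lapply(frontier, function(v)
        which(A[v, ] > 0)))), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) < n) next
    w <- sum(W[edges[sel, , drop = FALSE]])
    if (w > best) best <- w
  }
  best
}

# Exhaustive k-medoids (k = 2): best objective over all medoid pairs with
# greedy max-similarity assignment.
oracle_kmedoids2 <- function(W) {
  n <- nrow(W)
  best <- -Inf
  for (m1 in 1:(n - 1)) for (m2 in (m1 + 1):n) {
    obj <- 0
    for (v in 1:n) {
      if (v == m1 || v == m2) next
      obj <- obj + max(W[v, m1], W[v, m2])
    }
    if (obj > best) best <- obj
  }
  best
}

# Minimum normalized cut over all 2-splits.
oracle_min_ncut <- function(W) {
  n <- nrow(W)
  best <- Inf; best_side <- NULL
  vol <- function(S) sum(W[S, , drop = FALSE])
  for (mask in 1:(2^(n - 1) - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    Tt <- setdiff(1:n, S)
    cut <- sum(W[S, Tt, drop = FALSE])
    nc <- cut / vol(S) + cut / vol(Tt)
    if (nc < best) { best <- nc; best_side <- S }
  }
  list(ncut = best, side = best_side)
}

# Random symmetric weight matrix with given vertex count; weights drawn
# from `levels` (0 allowed).
random_W <- function(n, levels = c(0, 0.2, 0.5, 1.0)) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- sample(levels, n * (n - 1) / 2, replace = TRUE)
  W <- W + t(W)
  dimnames(W) <- list(paste0("v", 1:n), paste0("v", 1:n))
  W
}

# Tiny three-residue PDB text fixture (two chains worth of cases are built
# in the structure tests themselves).
tiny_pdb_lines <- function() {
  c("HEADER    SYNTHETIC FIXTURE",
    "ATOM      1  N   MET A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  MET A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLN A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ILE A   3       7.600   0.000   0.000  1.00  0.00           C",
    "TER",
    "END")
}

# Valid-alphabet toy sequences (the 20-letter alphabet has no B/J/O/U/X/Z).
toy_seqs <- function() {
  sequence_set(c("ACACA", "ACACA"), c("s1", "s2"))
}

# count components via the package-independent route used only in tests
graph_comp_count <- function(W) {
  n <- nrow(W)
  comp <- rep(0L, n); cur <- 0L
  for (v in 1:n) {
    if (comp[v] > 0) next
    cur <- cur + 1L
    frontier <- v
    while (length(frontier)) {
      comp[frontier] <- cur
      frontier <- setdiff(which(colSums(W[frontier, , drop = FALSE] > 0) > 0),
                          which(comp > 0))
    }
  }
  comp
}
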