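#' Jaccard co-occurrence score between two APCs
#'
#' `|Cseq1 int Cseq2| / |Cseq1 un Cseq2|` on the covered-sequence sets. When
#' both coverage sets are empty the score is 0 (0/0 convention) with a
#' warning.
#'
#' @param c1,c2 `aligned_pattern_cluster` objects, or plain character vectors
#'   of sequence ids.
#' @return a real in [0, 1].
#' @export
jaccard <- function(c1, c2) {
  a <- if (inherits(c1, "aligned_pattern_cluster")) c1$coverage else c1
  b <- if (inherits(c2, "aligned_pattern_cluster")) c2$coverage else c2
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both coverage sets empty; Jaccard taken as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Build the APC co-occurrence graph
#'
#' Vertices are APCs (in id order); the symmetric weight matrix W holds the
#' pairwise Jaccard co-occurrence scores with a zero diagonal, and the union
#' sizes `|Cseq1 un Cseq2|` are recorded for pair ranking.
#'
#' @param apcs list of `aligned_pattern_cluster` objects (at least 2).
#' @param edge_min optional sparsification threshold: weights strictly below
#'   it are zeroed (default 0, keep all positive edges).
#' @return object of class `cooccurrence_graph`: `ids`, `W`, `union_size`,
#'   `apcs`.
#' @export
build_graph <- function(apcs, edge_min = 0) {
  if (length(apcs) < 2L) stop("nothing to cluster: need at least 2 APCs")
  ids <- vapply(apcs, `[[`, character(1), "id")
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  U <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- apcs[[i]]$coverage; b <- apcs[[j]]$coverage
      u <- length(union(a, b))
      J <- if (u == 0L) 0 else length(intersect(a, b)) / u
      if (J < edge_min) J <- 0
      W[i, j] <- W[j, i] <- J
      U[i, j] <- U[j, i] <- u
    }
  }
  structure(list(ids = ids, W = W, union_size = U, apcs = apcs),
            class = "cooccurrence_graph")
}

#' Rank APC pairs by co-occurrence
#'
#' All unordered pairs sorted by Jaccard score descending; ties broken by
#' union size descending (a pair covering more sequences ranks higher), then
#' by lexicographic id pair. The order is total and deterministic.
#'
#' @param g a `cooccurrence_graph`.
#' @return data.frame with columns `apc_i`, `apc_j`, `score`, `union_size`.
#' @export
rank_pairs <- function(g) {
  stopifnot(inherits(g, "cooccurrence_graph"))
  n <- length(g$ids)
  pairs <- utils::combn(n, 2L)
  df <- data.frame(
    apc_i = g$ids[pairs[1L, ]],
    apc_j = g$ids[pairs[2L, ]],
    score = g$W[cbind(pairs[1L, ], pairs[2L, ])],
    union_size = g$union_size[cbind(pairs[1L, ], pairs[2L, ])],
    stringsAsFactors = FALSE)
  df <- df[order(-df$score, -df$union_size, df$apc_i, df$apc_j), ]
  rownames(df) <- NULL
  df
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  pos <- sum(x$W[upper.tri(x$W)] > 0)
  cat("cooccurrence_graph:", length(x$ids), "APCs,", pos,
      "positive edges\n")
  print(round(x$W, 3))
  invisible(x)
}
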