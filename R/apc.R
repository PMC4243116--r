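#' Merge constraints for aligned pattern clustering
#'
#' @param min_consecutive_column_match minimum number of consecutive aligned
#'   columns in which both merge partners contribute symbols and all non-gap
#'   symbols agree (default 3).
#' @param min_conserved_columns minimum number of fully identical columns
#'   (all rows, no gaps) the merged matrix must contain (default 1).
#' @param allow_relative_position_overlap if `FALSE` (default), two clusters
#'   may only merge when on every sequence they both cover their matched
#'   spans overlap by at least one position, i.e. they describe the same
#'   conserved region rather than adjacent or conflicting ones.
#' @param max_column_entropy optional per-column entropy cap in bits; columns
#'   above the cap are shown as the wildcard `*` in the consensus.
#' @return an `apc_constraints` list.
#' @export
apc_constraints <- function(min_consecutive_column_match = 3L,
                            min_conserved_columns = 1L,
                            allow_relative_position_overlap = FALSE,
                            max_column_entropy = NULL) {
  stopifnot(min_consecutive_column_match >= 0L, min_conserved_columns >= 0L)
  structure(list(min_consecutive_column_match = min_consecutive_column_match,
                 min_conserved_columns = min_conserved_columns,
                 allow_relative_position_overlap =
                   allow_relative_position_overlap,
                 max_column_entropy = max_column_entropy),
            class = "apc_constraints")
}

#' Globally align two patterns
#'
#' Needleman-Wunsch global alignment under Hamming-style scoring: +1 for an
#' identical column, 0 for a mismatch, `gap` (default -0.5) per gap symbol.
#' Among maximal-score alignments the one with fewest gaps is chosen, with
#' gaps placed rightmost; the result is deterministic. The wildcard `*`
#' matches any symbol.
#'
#' @param p,q non-empty pattern strings.
#' @param gap gap penalty (default -0.5).
#' @return list with `rows` (the two gapped strings, equal length), `score`,
#'   and `similarity` = identical columns / aligned length, in [0, 1].
#' @export
align_pattern_pair <- function(p, q, gap = -0.5) {
  stopifnot(nchar(p) >= 1L, nchar(q) >= 1L)
  a <- strsplit(p, "", fixed = TRUE)[[1]]
  b <- strsplit(q, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  # DP over (score, gap count), lexicographic: max score, then min gaps
  S <- matrix(0, n + 1L, m + 1L)
  G <- matrix(0L, n + 1L, m + 1L)
  S[1L, ] <- gap * (0:m); G[1L, ] <- 0:m
  S[, 1L] <- gap * (0:n); G[, 1L] <- 0:n
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      match <- as.numeric(a[i] == b[j] | a[i] == "*" | b[j] == "*")
      cand_s <- c(S[i, j] + match, S[i, j + 1L] + gap, S[i + 1L, j] + gap)
      cand_g <- c(G[i, j], G[i, j + 1L] + 1L, G[i + 1L, j] + 1L)
      best <- which(cand_s == max(cand_s))
      if (length(best) > 1L) best <- best[which.min(cand_g[best])]
      S[i + 1L, j + 1L] <- cand_s[best]
      G[i + 1L, j + 1L] <- cand_g[best]
    }
  }
  # traceback; preferring gap moves at ties pushes gaps toward the right end
  ra <- character(); rb <- character()
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    moved <- FALSE
    if (i > 0L) {  # gap in q
      if (isTRUE(all.equal(S[i + 1L, j + 1L], S[i, j + 1L] + gap)) &&
          G[i + 1L, j + 1L] == G[i, j + 1L] + 1L) {
        ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1L; moved <- TRUE
      }
    }
    if (!moved && j > 0L) {  # gap in p
      if (isTRUE(all.equal(S[i + 1L, j + 1L], S[i + 1L, j] + gap)) &&
          G[i + 1L, j + 1L] == G[i + 1L, j] + 1L) {
        ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1L; moved <- TRUE
      }
    }
    if (!moved) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1L; j <- j - 1L
    }
  }
  ident <- sum(ra == rb & ra != "-") +
    sum((ra == "*" | rb == "*") & ra != "-" & rb != "-" & ra != rb)
  len <- length(ra)
  list(rows = c(paste(ra, collapse = ""), paste(rb, collapse = "")),
       score = S[n + 1L, m + 1L], similarity = ident / len)
}

# Column entropy in bits over non-gap symbols; NA-free, 0 for all-gap column.
column_entropies <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    q <- table(col) / length(col)
    -sum(q * log2(q))
  })
}

# Consensus string: modal non-gap symbol per column (ties lexicographic);
# "*" where entropy exceeds the cap.
consensus_string <- function(rows, max_column_entropy = NULL) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ent <- column_entropies(rows)
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j][mat[, j] != "-"]
    if (length(col) == 0L) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1L]
  }, character(1))
  if (!is.null(max_column_entropy))
    cons[ent > max_column_entropy] <- "*"
  paste(cons, collapse = "")
}

# Build an aligned_pattern_cluster from gapped rows + member metadata.
new_apc <- function(id, rows, patterns, occurrences, support,
                    constraints = apc_constraints()) {
  stopifnot(length(rows) == length(patterns))
  degapped <- gsub("-", "", rows, fixed = TRUE)
  stopifnot(all(degapped == patterns))
  coverage <- sort(unique(unlist(lapply(occurrences, `[[`, "seq"))))
  x <- list(id = id,
            rows = rows,
            patterns = patterns,
            occurrences = occurrences,
            support = support,
            coverage = coverage,
            consensus = consensus_string(rows,
                                         constraints$max_column_entropy),
            column_entropy = column_entropies(rows))
  class(x) <- "aligned_pattern_cluster"
  x
}

#' @export
print.aligned_pattern_cluster <- function(x, ...) {
  cat("APC", x$id, ": ", length(x$patterns), " patterns x ",
      nchar(x$consensus), " columns, covers ", length(x$coverage),
      " sequences\n", sep = "")
  cat("  consensus:", x$consensus, "\n")
  for (r in x$rows) cat("           ", r, "\n")
  invisible(x)
}

# Per-sequence matched span (1-based inclusive) of an APC: min start to max
# end over all member-pattern occurrences on that sequence.
apc_spans <- function(apc) {
  occ <- do.call(rbind, lapply(seq_along(apc$patterns), function(i) {
    o <- apc$occurrences[[i]]
    if (is.null(o) || nrow(o) == 0L) return(NULL)
    data.frame(seq = o$seq, start = o$start,
               end = o$start + nchar(apc$patterns[i]) - 1L)
  }))
  if (is.null(occ)) return(NULL)
  starts <- tapply(occ$start, occ$seq, min)
  ends <- tapply(occ$end, occ$seq, max)
  data.frame(seq = names(starts), start = as.integer(starts),
             end = as.integer(ends[names(starts)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sequences covered by an APC
#'
#' Recomputes, by direct substring scan of the sequence set, the ids of
#' sequences containing at least one occurrence of at least one member
#' pattern. This is the coverage set `Cseq` used by the Jaccard
#' co-occurrence score.
#'
#' @param apc an `aligned_pattern_cluster`.
#' @param seqs the [sequence_set] the patterns were discovered from.
#' @return sorted character vector of sequence ids.
#' @export
apc_coverage <- function(apc, seqs) {
  stopifnot(inherits(apc, "aligned_pattern_cluster"),
            inherits(seqs, "sequence_set"))
  hit <- vapply(seqs$residues, function(s)
    any(vapply(apc$patterns, function(p) grepl(p, s, fixed = TRUE),
               logical(1))), logical(1))
  sort(seqs$id[hit])
}

# Admissibility of a merged matrix under the constraints.
merge_admissible <- function(rows_a, rows_b, apc_a, apc_b, constraints) {
  rows <- c(rows_a, rows_b)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  na <- length(rows_a)
  ncols <- ncol(mat)
  # consecutive columns where both sides contribute and all non-gap agree
  match_col <- vapply(seq_len(ncols), function(j) {
    ca <- mat[seq_len(na), j]; cb <- mat[-seq_len(na), j]
    ca <- ca[ca != "-"]; cb <- cb[cb != "-"]
    length(ca) > 0L && length(cb) > 0L &&
      length(unique(c(ca, cb))) == 1L
  }, logical(1))
  runs <- rle(match_col)
  best_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (best_run < constraints$min_consecutive_column_match) return(FALSE)
  conserved <- vapply(seq_len(ncols), function(j) {
    col <- mat[, j]
    all(col != "-") && length(unique(col)) == 1L
  }, logical(1))
  if (sum(conserved) < constraints$min_conserved_columns) return(FALSE)
  if (!is.null(constraints$max_column_entropy)) {
    if (any(column_entropies(rows) > constraints$max_column_entropy))
      return(FALSE)
  }
  if (!constraints$allow_relative_position_overlap) {
    sa <- apc_spans(apc_a); sb <- apc_spans(apc_b)
    shared <- intersect(sa$seq, sb$seq)
    for (s in shared) {
      ia <- sa[sa$seq == s, ]; ib <- sb[sb$seq == s, ]
      if (min(ia$end, ib$end) < max(ia$start, ib$start)) return(FALSE)
    }
  }
  TRUE
}

# Merge two APCs via consensus-consensus alignment; returns NULL when the
# merged matrix violates the constraints.
merge_apcs <- function(a, b, constraints, gap = -0.5) {
  al <- align_pattern_pair(a$consensus, b$consensus, gap = gap)
  expand <- function(rows, gapped_consensus) {
    tpl <- strsplit(gapped_consensus, "", fixed = TRUE)[[1]]
    vapply(rows, function(r) {
      rc <- strsplit(r, "", fixed = TRUE)[[1]]
      out <- character(length(tpl)); k <- 1L
      for (t in seq_along(tpl)) {
        if (tpl[t] == "-") out[t] <- "-"
        else { out[t] <- rc[k]; k <- k + 1L }
      }
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  rows_a <- expand(a$rows, al$rows[1L])
  rows_b <- expand(b$rows, al$rows[2L])
  if (!merge_admissible(rows_a, rows_b, a, b, constraints)) return(NULL)
  new_apc(id = a$id,
          rows = c(rows_a, rows_b),
          patterns = c(a$patterns, b$patterns),
          occurrences = c(a$occurrences, b$occurrences),
          support = length(unique(c(a$coverage, b$coverage))),
          constraints = constraints)
}

#' Group patterns into Aligned Pattern Clusters
#'
#' Greedy agglomerative merging: starting from one single-pattern cluster per
#' discovered pattern, the highest-similarity admissible pair of clusters is
#' merged repeatedly until none remains. Similarity is the normalized global
#' alignment similarity of cluster consensi ([align_pattern_pair]); a merge
#' is admissible under the [apc_constraints]. Tie-break: higher combined
#' support, then lexicographically smallest consensus pair. Deterministic
#' given input order.
#'
#' @param patterns a `pattern_set` from [discover_patterns] (or any
#'   data.frame with `pattern` and `support` and an `occurrences` attribute).
#' @param constraints an [apc_constraints] object.
#' @param gap gap penalty passed to the aligner.
#' @return list of `aligned_pattern_cluster` objects, ids `APC1`, `APC2`, ...
#'   ordered by coverage size descending then consensus.
#' @export
cluster_patterns <- function(patterns, constraints = apc_constraints(),
                             gap = -0.5) {
  stopifnot(nrow(patterns) >= 1L)
  occs <- attr(patterns, "occurrences")
  clusters <- lapply(seq_len(nrow(patterns)), function(i) {
    p <- patterns$pattern[i]
    new_apc(id = paste0("P", i), rows = p, patterns = p,
            occurrences = occs[p], support = patterns$support[i],
            constraints = constraints)
  })
  nc <- length(clusters)
  # cached pairwise state; entries reset for rows touched by a merge
  sim <- matrix(NA_real_, nc, nc)
  blocked <- matrix(FALSE, nc, nc)
  alive <- rep(TRUE, nc)
  pair_sim <- function(i, j) {
    if (is.na(sim[i, j])) {
      s <- align_pattern_pair(clusters[[i]]$consensus,
                              clusters[[j]]$consensus,
                              gap = gap)$similarity
      sim[i, j] <<- s; sim[j, i] <<- s
    }
    sim[i, j]
  }
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    pairs <- utils::combn(idx, 2L)
    keep <- !blocked[cbind(pairs[1L, ], pairs[2L, ])]
    pairs <- pairs[, keep, drop = FALSE]
    if (ncol(pairs) == 0L) break
    s <- vapply(seq_len(ncol(pairs)), function(r)
      pair_sim(pairs[1L, r], pairs[2L, r]), numeric(1))
    comb <- vapply(seq_len(ncol(pairs)), function(r)
      length(unique(c(clusters[[pairs[1L, r]]]$coverage,
                      clusters[[pairs[2L, r]]]$coverage))), integer(1))
    cons <- vapply(seq_len(ncol(pairs)), function(r)
      paste(sort(c(clusters[[pairs[1L, r]]]$consensus,
                   clusters[[pairs[2L, r]]]$consensus)), collapse = "\r"),
      character(1))
    ord <- order(-s, -comb, cons)
    merged <- NULL
    for (r in ord) {
      i <- pairs[1L, r]; j <- pairs[2L, r]
      m <- merge_apcs(clusters[[i]], clusters[[j]], constraints, gap)
      if (is.null(m)) {
        blocked[i, j] <- TRUE; blocked[j, i] <- TRUE
      } else {
        merged <- m
        break
      }
    }
    if (is.null(merged)) break
    clusters[[i]] <- merged
    alive[j] <- FALSE
    sim[i, ] <- NA_real_; sim[, i] <- NA_real_
    blocked[i, ] <- FALSE; blocked[, i] <- FALSE
  }
  clusters <- clusters[alive]
  sizes <- vapply(clusters, function(c) length(c$coverage), integer(1))
  cons <- vapply(clusters, `[[`, character(1), "consensus")
  clusters <- clusters[order(-sizes, cons)]
  for (i in seq_along(clusters)) clusters[[i]]$id <- paste0("APC", i)
  clusters
}
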