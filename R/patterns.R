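#' Enumerate candidate patterns
#'
#' Finds every contiguous substring with length in `[min_len, max_len]`
#' whose sequence-level support (number of distinct sequences containing at
#' least one occurrence) reaches `min_occurrence`. All occurrences are
#' recorded, including overlapping self-occurrences; support de-duplicates
#' per sequence.
#'
#' Enumeration exploits the anti-monotonicity of support: a window of length
#' L > `min_len` can only be frequent if its `min_len`-prefix is frequent, so
#' longer windows are generated from surviving prefix positions only. The
#' result is identical to exhaustive window counting.
#'
#' @param seqs a [sequence_set].
#' @param min_len,max_len pattern length bounds; `max_len = NULL` means
#'   unbounded (up to the longest sequence).
#' @param min_occurrence minimum sequence-level support.
#' @return data.frame with columns `pattern`, `length`, `support`,
#'   `occ_count`, plus an `occurrences` attribute: a named list of
#'   data.frames (`seq`, `start`, 1-based) keyed by pattern.
#' @export
enumerate_candidates <- function(seqs, min_len, max_len = NULL,
                                 min_occurrence = 1L) {
  stopifnot(inherits(seqs, "sequence_set"), min_len >= 1L,
            min_occurrence >= 1L)
  lens <- nchar(seqs$residues)
  if (is.null(max_len)) max_len <- max(lens)
  stopifnot(min_len <= max_len)
  if (min_len > max(lens)) {
    warning("min_len exceeds the longest sequence; no candidates")
    return(empty_candidates())
  }

  windows_at <- function(L, keep = NULL) {
    # keep: named (by seq index) list of admissible start positions, or NULL
    out <- vector("list", length(seqs$id))
    for (i in seq_along(seqs$id)) {
      n <- lens[i]
      if (n < L) next
      starts <- if (is.null(keep)) seq_len(n - L + 1L) else
        keep[[i]][keep[[i]] <= n - L + 1L]
      if (length(starts) == 0L) next
      out[[i]] <- data.frame(
        pattern = substring(seqs$residues[i], starts, starts + L - 1L),
        seq = seqs$id[i], start = starts, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  frequent <- function(occ) {
    if (is.null(occ) || nrow(occ) == 0L) return(NULL)
    first <- !duplicated(paste0(occ$pattern, "\r", occ$seq))
    supp <- table(occ$pattern[first])
    keep <- names(supp)[supp >= min_occurrence]
    if (length(keep) == 0L) return(NULL)
    occ[occ$pattern %in% keep, , drop = FALSE]
  }

  base_occ <- frequent(windows_at(min_len))
  all_occ <- list(base_occ)
  if (!is.null(base_occ) && max_len > min_len) {
    seed <- split(base_occ$start, factor(base_occ$seq, levels = seqs$id))
    for (L in seq(min_len + 1L, max_len)) {
      occ <- frequent(windows_at(L, keep = seed))
      if (is.null(occ)) break
      all_occ[[length(all_occ) + 1L]] <- occ
    }
  }
  occ <- do.call(rbind, all_occ)
  if (is.null(occ) || nrow(occ) == 0L) {
    warning("no candidate pattern reaches min_occurrence = ", min_occurrence)
    return(empty_candidates())
  }
  first <- !duplicated(paste0(occ$pattern, "\r", occ$seq))
  supp <- table(occ$pattern[first])
  cnt <- table(occ$pattern)
  pat <- sort(names(supp))
  df <- data.frame(pattern = pat, length = nchar(pat),
                   support = as.integer(supp[pat]),
                   occ_count = as.integer(cnt[pat]),
                   stringsAsFactors = FALSE)
  occ_list <- split(occ[c("seq", "start")], occ$pattern)
  attr(df, "occurrences") <- occ_list[df$pattern]
  df
}

empty_candidates <- function() {
  df <- data.frame(pattern = character(), length = integer(),
                   support = integer(), occ_count = integer(),
                   stringsAsFactors = FALSE)
  attr(df, "occurrences") <- list()
  df
}

#' Pattern significance (standard residual)
#'
#' Scores a pattern against an order-0 independent-residue background:
#' \deqn{z = (O - E) / \sqrt{E}}
#' where O is the total occurrence count of the pattern over all windows of
#' the set, and E = W_n * prod(f(p_i)) with W_n the total number of length-n
#' windows and f the background residue frequencies.
#'
#' @param pattern pattern string over the amino-acid alphabet.
#' @param seqs a [sequence_set].
#' @param occ_count optional precomputed total occurrence count; counted by
#'   scanning when missing.
#' @return the standard residual z (or `Inf` with a warning when a residue of
#'   the pattern is absent from the background).
#' @export
significance_score <- function(pattern, seqs, occ_count = NULL) {
  stopifnot(inherits(seqs, "sequence_set"), nchar(pattern) >= 1L)
  n <- nchar(pattern)
  lens <- nchar(seqs$residues)
  W_n <- sum(pmax(lens - n + 1L, 0L))
  f <- seqs$freq[strsplit(pattern, "", fixed = TRUE)[[1]]]
  E <- W_n * prod(f)
  if (is.null(occ_count)) occ_count <- count_occurrences(pattern, seqs)
  if (E == 0) {
    warning("pattern '", pattern, "' contains a residue absent from the ",
            "background; significance is infinite")
    return(Inf)
  }
  (occ_count - E) / sqrt(E)
}

# Total (overlapping) occurrence count of a literal pattern over all sequences.
count_occurrences <- function(pattern, seqs) {
  n <- 0L
  for (s in seqs$residues) {
    hits <- find_overlapping(pattern, s)
    n <- n + length(hits)
  }
  n
}

# All 1-based start positions of literal `pattern` in `s`, overlaps included.
find_overlapping <- function(pattern, s, fixed = TRUE) {
  hits <- integer()
  from <- 1L
  repeat {
    m <- regexpr(pattern, substring(s, from), fixed = fixed, perl = !fixed)
    if (m == -1L) break
    hit <- from + as.integer(m) - 1L
    hits <- c(hits, hit)
    from <- hit + 1L
  }
  hits
}

#' Delta-closed pattern pruning
#'
#' Removes redundant patterns: a pattern p is pruned iff some retained
#' contiguous super-pattern q (p a strict substring of q) keeps at least a
#' `delta` fraction of p's support, i.e. `support(q) >= delta * support(p)`.
#' Patterns are processed from longest to shortest so retention is
#' well-defined; the operation is idempotent.
#'
#' @param candidates candidate data.frame from [enumerate_candidates] (with
#'   its `occurrences` attribute).
#' @param delta redundancy fraction in (0, 1].
#' @return the retained subset, same shape as the input, plus a `pruned`
#'   attribute naming each removed pattern and the super-pattern responsible.
#' @export
delta_closed_prune <- function(candidates, delta = 0.9) {
  stopifnot(is.data.frame(candidates), delta > 0, delta <= 1)
  if (nrow(candidates) == 0L) return(candidates)
  occs <- attr(candidates, "occurrences")
  ord <- order(-candidates$length, candidates$pattern)
  cand <- candidates[ord, , drop = FALSE]
  retained <- character()
  ret_support <- integer()
  pruned_by <- character()
  pruned <- character()
  for (i in seq_len(nrow(cand))) {
    p <- cand$pattern[i]
    sup_p <- cand$support[i]
    killer <- NA_character_
    longer <- retained[nchar(retained) > nchar(p)]
    for (q in longer) {
      if (grepl(p, q, fixed = TRUE) &&
          ret_support[[q]] >= delta * sup_p) {
        killer <- q
        break
      }
    }
    if (is.na(killer)) {
      retained <- c(retained, p)
      ret_support[[p]] <- sup_p
    } else {
      pruned <- c(pruned, p)
      pruned_by <- c(pruned_by, killer)
    }
  }
  keep <- candidates$pattern %in% retained
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "occurrences") <- occs[out$pattern]
  attr(out, "pruned") <- data.frame(pattern = pruned, pruned_by = pruned_by,
                                    stringsAsFactors = FALSE)
  out
}

#' Discover statistically significant patterns
#'
#' Full pattern-discovery stage: candidate enumeration, significance
#' filtering by standard residual, and delta-closed pruning. The result is
#' sorted by support descending, then lexicographically.
#'
#' @param seqs a [sequence_set].
#' @param min_len,max_len pattern length bounds (`max_len = NULL` for
#'   unbounded).
#' @param min_occurrence minimum sequence-level support.
#' @param delta delta-closed pruning fraction in (0, 1].
#' @param z_threshold minimum standard residual (default 1.96, the two-sided
#'   5% normal critical value).
#' @return an object of class `pattern_set`: the retained pattern data.frame
#'   (columns `pattern`, `length`, `support`, `occ_count`, `z`), with
#'   attributes `occurrences`, `pruned` and `config`.
#' @export
discover_patterns <- function(seqs, min_len = 5L, max_len = 15L,
                              min_occurrence = 20L, delta = 0.9,
                              z_threshold = 1.96) {
  cand <- enumerate_candidates(seqs, min_len, max_len, min_occurrence)
  if (nrow(cand) > 0L) {
    z <- vapply(seq_len(nrow(cand)), function(i)
      significance_score(cand$pattern[i], seqs, cand$occ_count[i]),
      numeric(1))
    cand$z <- z
    keep <- z >= z_threshold
    occs <- attr(cand, "occurrences")
    cand <- cand[keep, , drop = FALSE]
    attr(cand, "occurrences") <- occs[cand$pattern]
  } else {
    cand$z <- numeric(0)
  }
  out <- delta_closed_prune(cand, delta)
  ord <- order(-out$support, out$pattern)
  occs <- attr(out, "occurrences")
  pruned <- attr(out, "pruned")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "occurrences") <- occs[out$pattern]
  attr(out, "pruned") <- pruned
  attr(out, "config") <- list(min_len = min_len, max_len = max_len,
                              min_occurrence = min_occurrence, delta = delta,
                              z_threshold = z_threshold)
  if (nrow(out) == 0L) warning("no significant pattern retained")
  class(out) <- c("pattern_set", "data.frame")
  out
}

#' @export
print.pattern_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("pattern_set:", nrow(x), "patterns")
  if (!is.null(cfg))
    cat(sprintf(" (len %d-%s, min support %d, delta %.2f, z >= %.2f)",
                cfg$min_len, ifelse(is.null(cfg$max_len), "Inf",
                                    as.character(cfg$max_len)),
                cfg$min_occurrence, cfg$delta, cfg$z_threshold))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}
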