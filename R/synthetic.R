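#' Specification of a synthetic protein family
#'
#' Describes a family of background sequences with planted conserved motifs
#' whose presence across sequences follows a configurable co-occurrence
#' design: motifs in the same joint group are present together (one Bernoulli
#' draw per group per sequence), independent motifs draw independently.
#' Present motifs are implanted at fixed sites, replacing background
#' residues so truth coordinates stay exact, then point mutations (and,
#' optionally, indels in the background segments) are applied.
#'
#' The defaults are the package's reference study conditions: 100 sequences
#' of length 150 with two jointly occurring 10-residue motifs (group
#' presence probability 0.7) and one independent 10-residue motif
#' (probability 0.7), per-position mutation rate 0.05, no indels, uniform
#' background.
#'
#' @param n_sequences number of sequences.
#' @param length sequence length before indels.
#' @param motifs data.frame with columns `name`, `consensus`, `site`
#'   (1-based implant start) and `mutation_rate`.
#' @param groups list of co-occurrence groups, each
#'   `list(motifs = <names>, p = <presence probability>)`; a group with a
#'   single motif is an independent motif.
#' @param background named residue frequency vector (default uniform over
#'   the 20-letter alphabet).
#' @param indel_rate per-position insertion/deletion probability applied to
#'   background segments only (default 0).
#' @param seed RNG seed; a fixed seed makes generated FASTA/PDB output
#'   byte-identical across runs.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences = 100L,
                           length = 150L,
                           motifs = data.frame(
                             name = c("jointA", "jointB", "indep"),
                             consensus = c("WKDGHNVFTR", "CPAYQELMSG",
                                           "LRHTEWIKQD"),
                             site = c(15L, 65L, 115L),
                             mutation_rate = 0.05,
                             stringsAsFactors = FALSE),
                           groups = list(
                             list(motifs = c("jointA", "jointB"), p = 0.7),
                             list(motifs = "indep", p = 0.7)),
                           background = NULL,
                           indel_rate = 0,
                           seed = 1L) {
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(n_sequences >= 1L, length >= 1L,
            all(nchar(motifs$consensus) < length),
            all(motifs$site >= 1L),
            all(motifs$site + nchar(motifs$consensus) - 1L <= length),
            all(motifs$mutation_rate >= 0 & motifs$mutation_rate <= 1),
            indel_rate >= 0, indel_rate <= 1,
            abs(sum(background) - 1) < 1e-9)
  ps <- vapply(groups, `[[`, numeric(1), "p")
  stopifnot(all(ps >= 0 & ps <= 1))
  grouped <- unlist(lapply(groups, `[[`, "motifs"))
  stopifnot(setequal(grouped, motifs$name), !anyDuplicated(grouped))
  # implant sites must not overlap
  ord <- order(motifs$site)
  ends <- motifs$site[ord] + nchar(motifs$consensus[ord]) - 1L
  if (any(motifs$site[ord][-1L] <= ends[-length(ends)]))
    stop("motif implant sites overlap")
  structure(list(n_sequences = n_sequences, length = length,
                 motifs = motifs, groups = groups, background = background,
                 indel_rate = indel_rate, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic protein family
#'
#' Draws the family described by a [synthetic_spec] and records the ground
#' truth: which motifs are present on each sequence and at what positions.
#'
#' @param spec a [synthetic_spec].
#' @return list with `seqs` (a [sequence_set]) and `truth` (class
#'   `synthetic_truth`): `presence` (logical matrix sequences x motifs),
#'   `positions` (data.frame `seq`, `motif`, `start`, `end`), `motifs`,
#'   `groups`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, generate_family_impl(spec))
}

generate_family_impl <- function(spec) {
  n <- spec$n_sequences
  ids <- sprintf("syn%03d", seq_len(n))
  motifs <- spec$motifs[order(spec$motifs$site), , drop = FALSE]
  presence <- matrix(FALSE, n, nrow(motifs),
                     dimnames = list(ids, motifs$name))
  seqs <- character(n)
  pos_rows <- list()
  mutate <- function(m, rate) {
    chars <- strsplit(m, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < rate
    for (i in which(hit))
      chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
    paste(chars, collapse = "")
  }
  bg_draw <- function(len) {
    if (len <= 0L) return("")
    paste(sample(AA_ALPHABET, len, replace = TRUE,
                 prob = spec$background), collapse = "")
  }
  apply_indels <- function(s, rate) {
    if (rate == 0 || !nzchar(s)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    for (ch in chars) {
      u <- stats::runif(1)
      if (u < rate / 2) next                       # deletion
      out <- c(out, ch)
      if (u >= rate / 2 && u < rate)               # insertion after
        out <- c(out, sample(AA_ALPHABET, 1L, prob = spec$background))
    }
    paste(out, collapse = "")
  }
  for (i in seq_len(n)) {
    for (g in spec$groups) {
      if (stats::runif(1) < g$p) presence[i, g$motifs] <- TRUE
    }
    # build the sequence as background segments interleaved with motifs
    pieces <- character(0)
    pos <- 1L   # cursor in nominal coordinates
    out_len <- 0L
    for (m in seq_len(nrow(motifs))) {
      site <- motifs$site[m]
      mlen <- nchar(motifs$consensus[m])
      seg <- apply_indels(bg_draw(site - pos), spec$indel_rate)
      pieces <- c(pieces, seg)
      out_len <- out_len + nchar(seg)
      if (presence[i, motifs$name[m]]) {
        imp <- mutate(motifs$consensus[m], motifs$mutation_rate[m])
        pos_rows[[length(pos_rows) + 1L]] <- data.frame(
          seq = ids[i], motif = motifs$name[m],
          start = out_len + 1L, end = out_len + mlen,
          stringsAsFactors = FALSE)
      } else {
        imp <- bg_draw(mlen)  # background filler keeps length constant
      }
      pieces <- c(pieces, imp)
      out_len <- out_len + mlen
      pos <- site + mlen
    }
    tail_seg <- apply_indels(bg_draw(spec$length - pos + 1L),
                             spec$indel_rate)
    pieces <- c(pieces, tail_seg)
    seqs[i] <- paste(pieces, collapse = "")
  }
  truth <- structure(list(presence = presence,
                          positions = do.call(rbind, pos_rows),
                          motifs = motifs, groups = spec$groups,
                          ids = ids),
                     class = "synthetic_truth")
  list(seqs = sequence_set(seqs, ids), truth = truth)
}

#' Synthetic C-alpha structure for a family member
#'
#' Builds a C-alpha trace (exact 3.8 Angstrom consecutive spacing) for one
#' sequence of a generated family. Under `"colocated"` geometry the planted
#' motif regions are folded into a common ball of about 15 Angstrom while
#' the linkers make long excursions away from it; under `"dispersed"` the
#' chain is extended, so motif regions separated in sequence are at least
#' 40 Angstrom apart in space. The structure can be written with
#' [write_pdb] and re-read with [read_structure].
#'
#' @param truth a `synthetic_truth` from [generate_family].
#' @param seqs the matching [sequence_set].
#' @param seq_id id of the member sequence to trace.
#' @param geometry `"colocated"` or `"dispersed"`.
#' @param seed RNG seed for the confined-walk directions (default 1).
#' @return a `structure_model` (single chain "A").
#' @export
generate_structure_for <- function(truth, seqs, seq_id,
                                   geometry = c("colocated", "dispersed"),
                                   seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(truth, "synthetic_truth"), seq_id %in% seqs$id)
  s <- seqs$residues[match(seq_id, seqs$id)]
  n <- nchar(s)
  pos <- truth$positions
  pos <- pos[pos$seq == seq_id, , drop = FALSE]
  in_motif <- rep(FALSE, n)
  for (r in seq_len(nrow(pos)))
    in_motif[pos$start[r]:pos$end[r]] <- TRUE
  step <- 3.8
  coords <- matrix(NA_real_, n, 3)
  if (geometry == "dispersed") {
    coords[, 1] <- (seq_len(n) - 1L) * step
    coords[, 2] <- 0
    coords[, 3] <- 0
  } else {
    coords <- with_local_seed(seed, {
      colocated_trace(n, in_motif, step)
    })
  }
  atoms <- data.frame(chain = "A", resno = seq_len(n),
                      resid = unname(AA3[strsplit(s, "")[[1]]]),
                      aa = strsplit(s, "")[[1]],
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      seqpos = seq_len(n), stringsAsFactors = FALSE)
  structure(list(id = paste0("synthetic_", seq_id, "_", geometry),
                 atoms = atoms,
                 chains = stats::setNames(s, "A")),
            class = "structure_model")
}

# Chain trace: motif residues do a confined walk inside a ball of radius
# `r_core` around the origin; each linker makes an out-and-back excursion in
# its own direction, returning to the core before the next motif.
colocated_trace <- function(n, in_motif, step, r_core = 6, r_out = 45) {
  coords <- matrix(0, n, 3)
  cur <- c(r_core / 2, 0, 0)
  coords[1L, ] <- cur
  # segment boundaries
  runs <- rle(in_motif)
  seg_end <- cumsum(runs$lengths)
  seg_start <- c(1L, utils::head(seg_end, -1L) + 1L)
  excursion_dir <- 0
  confined_step <- function(cur) {
    # stay near the origin: bounce back when outside the core ball
    if (sqrt(sum(cur^2)) > r_core) {
      dir <- -cur / sqrt(sum(cur^2))
      jitter <- stats::rnorm(3, 0, 0.3)
      dir <- dir + jitter
    } else {
      dir <- stats::rnorm(3)
    }
    dir <- dir / sqrt(sum(dir^2))
    cur + step * dir
  }
  i <- 2L
  for (sgi in seq_along(runs$values)) {
    from <- max(seg_start[sgi], 2L); to <- seg_end[sgi]
    if (from > to) next
    if (runs$values[sgi]) {         # motif: confined near origin
      for (j in from:to) {
        cur <- confined_step(cur)
        coords[j, ] <- cur
      }
    } else {                        # linker: out-and-back excursion
      len <- to - from + 1L
      excursion_dir <- excursion_dir + 2.399963  # golden angle
      u <- c(cos(excursion_dir), sin(excursion_dir), 0.2)
      u <- u / sqrt(sum(u^2))
      out_steps <- min(len %/% 2L, ceiling(r_out / step))
      for (j in from:to) {
        done <- j - from + 1L
        if (done <= out_steps) {
          cur <- cur + step * u
        } else if (sqrt(sum(cur^2)) > r_core) {
          dir <- -cur / sqrt(sum(cur^2)) + stats::rnorm(3, 0, 0.1)
          dir <- dir / sqrt(sum(dir^2))
          cur <- cur + step * dir
        } else {
          cur <- confined_step(cur)
        }
        coords[j, ] <- cur
      }
    }
  }
  coords
}

#' Empirical co-occurrence of planted motifs
#'
#' Jaccard index of the presence sets of two motifs, computed directly from
#' the truth table.
#'
#' @param truth a `synthetic_truth`.
#' @param m1,m2 motif names.
#' @return real in [0, 1].
#' @export
truth_jaccard <- function(truth, m1, m2) {
  a <- truth$ids[truth$presence[, m1]]
  b <- truth$ids[truth$presence[, m2]]
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Match APCs to the planted motifs
#'
#' Assigns each APC to the planted motif whose implanted spans its member
#' occurrences overlap most often, or `NA` when fewer than half of the
#' occurrences fall on any planted motif.
#'
#' @param apcs list of `aligned_pattern_cluster` objects.
#' @param truth a `synthetic_truth`.
#' @return named character vector, APC id -> motif name (or `NA`).
#' @export
match_apcs_to_truth <- function(apcs, truth) {
  pos <- truth$positions
  out <- stats::setNames(rep(NA_character_, length(apcs)),
                         vapply(apcs, `[[`, character(1), "id"))
  for (a in apcs) {
    occ <- do.call(rbind, lapply(seq_along(a$patterns), function(i) {
      o <- a$occurrences[[i]]
      data.frame(seq = o$seq, start = o$start,
                 end = o$start + nchar(a$patterns[i]) - 1L)
    }))
    votes <- stats::setNames(numeric(nrow(truth$motifs)),
                             truth$motifs$name)
    for (r in seq_len(nrow(occ))) {
      hit <- pos[pos$seq == occ$seq[r] &
                   pos$start <= occ$end[r] & pos$end >= occ$start[r], ]
      if (nrow(hit) > 0) votes[hit$motif[1L]] <- votes[hit$motif[1L]] + 1
    }
    if (sum(votes) >= nrow(occ) / 2)
      out[a$id] <- names(votes)[which.max(votes)]
  }
  out
}
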