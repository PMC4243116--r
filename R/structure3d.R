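# three-letter <-> one-letter residue name mapping (standard 20)
AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")
AA1 <- stats::setNames(names(AA3), AA3)

#' Read a protein structure from a PDB file
#'
#' Parses the first model of a PDB file, keeping one C-alpha coordinate per
#' residue of each polymer chain. Hetero records and waters are excluded;
#' when a C-alpha has alternate locations, the highest-occupancy one is
#' kept; residues lacking a C-alpha are skipped with a warning.
#'
#' @param path path to a PDB-format file.
#' @return an object of class `structure_model`: `id` (file stem), `atoms`
#'   (data.frame `chain`, `resno`, `resid`, `aa`, `x`, `y`, `z`, one row per
#'   residue in chain order; `seqpos` is the 1-based sequential index within
#'   the chain), and `chains` (named character vector of one-letter chain
#'   sequences).
#' @export
read_structure <- function(path) {
  stopifnot(file.exists(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms in '", path, "'")
  # one CA per (chain, resno, insert): keep highest occupancy
  key <- paste(ca$chain, ca$resno, ca$insert)
  ca <- ca[order(key, -replace(ca$o, is.na(ca$o), 1)), , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert)), , drop = FALSE]
  # restore file order
  ca <- ca[order(as.integer(rownames(ca))), , drop = FALSE]
  aa <- unname(AA1[ca$resid])
  drop <- is.na(aa)
  if (any(drop)) {
    warning("skipped ", sum(drop), " residue(s) with non-standard names: ",
            paste(unique(ca$resid[drop]), collapse = ", "))
    ca <- ca[!drop, , drop = FALSE]
    aa <- aa[!drop]
  }
  atoms <- data.frame(chain = ca$chain, resno = ca$resno, resid = ca$resid,
                      aa = aa, x = ca$x, y = ca$y, z = ca$z,
                      stringsAsFactors = FALSE)
  atoms$seqpos <- stats::ave(seq_len(nrow(atoms)), atoms$chain,
                             FUN = seq_along)
  chains <- vapply(split(atoms$aa, atoms$chain), paste, character(1),
                   collapse = "")
  structure(list(id = sub("\\.[^.]*$", "", basename(path)), atoms = atoms,
                 chains = chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model ", x$id, ": ", nrow(x$atoms), " residues in ",
      length(x$chains), " chain(s) [",
      paste(names(x$chains), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Write a C-alpha trace to a PDB file
#'
#' Emits one ATOM record per residue (C-alpha only), standard fixed-width
#' PDB columns, terminated by TER/END. Used for the synthetic structures.
#'
#' @param s a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  a <- s$atoms
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(a)), AA3[a$aa], a$chain, a$resno, a$x, a$y, a$z)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# Match positions (1-based starts) of a motif string over Sigma+{*} in a
# chain sequence; "*" matches any residue, gaps must be removed beforehand.
scan_chain <- function(motif, chain_seq) {
  if (grepl("*", motif, fixed = TRUE)) {
    rx <- gsub("\\*", ".", motif)
    find_overlapping(rx, chain_seq, fixed = FALSE)
  } else {
    find_overlapping(motif, chain_seq, fixed = TRUE)
  }
}

#' Map an APC onto a structure chain
#'
#' Scans each member pattern (gaps removed) and the APC consensus against
#' the chain sequence; the wildcard `*` matches any residue. Matched spans
#' are merged when overlapping. If no full pattern matches, maximal partial
#' matches of length at least `min_partial` are accepted, so that parts of
#' an APC can still anchor it on the structure.
#'
#' @param apc an `aligned_pattern_cluster`.
#' @param s a `structure_model`.
#' @param chain chain id; default `NULL` picks the chain with the most full
#'   pattern matches (first chain on ties).
#' @param min_partial minimum length of an accepted partial match
#'   (default 5).
#' @return data.frame of merged regions (`chain`, `start`, `end`, 1-based
#'   sequential positions within the chain), or a zero-row frame when the
#'   APC cannot be mapped (with a warning).
#' @export
map_apc_to_structure <- function(apc, s, chain = NULL, min_partial = 5L) {
  stopifnot(inherits(apc, "aligned_pattern_cluster"),
            inherits(s, "structure_model"))
  motifs <- unique(c(apc$patterns, gsub("-", "", apc$consensus, fixed = TRUE)))
  if (is.null(chain)) {
    hits_per_chain <- vapply(s$chains, function(cs)
      sum(vapply(motifs, function(m) length(scan_chain(m, cs)), integer(1))),
      integer(1))
    chain <- if (any(hits_per_chain > 0)) {
      names(s$chains)[which.max(hits_per_chain)]
    } else names(s$chains)[1L]
  }
  cs <- s$chains[[chain]]
  spans <- NULL
  for (m in motifs) {
    starts <- scan_chain(m, cs)
    if (length(starts) > 0)
      spans <- rbind(spans, data.frame(start = starts,
                                       end = starts + nchar(m) - 1L))
  }
  if (is.null(spans)) {
    # fall back to maximal partial matches of the member patterns
    lengths_desc <- seq_len(max(nchar(motifs)) - 1L)
    lengths_desc <- rev(lengths_desc[lengths_desc >= min_partial])
    for (L in lengths_desc) {
      for (m in motifs[nchar(motifs) > L]) {
        for (off in seq_len(nchar(m) - L + 1L)) {
          sub <- substr(m, off, off + L - 1L)
          starts <- scan_chain(sub, cs)
          if (length(starts) > 0)
            spans <- rbind(spans, data.frame(start = starts,
                                             end = starts + L - 1L))
        }
      }
      if (!is.null(spans)) break
    }
  }
  if (is.null(spans)) {
    warning("APC ", apc$id, " has no match of length >= ", min_partial,
            " on chain ", chain, "; unmapped")
    return(data.frame(chain = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  spans <- merge_spans(spans)
  data.frame(chain = chain, start = spans$start, end = spans$end,
             stringsAsFactors = FALSE)
}

# Merge overlapping/adjacent [start, end] spans.
merge_spans <- function(spans) {
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  out <- spans[1L, , drop = FALSE]
  if (nrow(spans) > 1L) for (i in seq(2L, nrow(spans))) {
    last <- nrow(out)
    if (spans$start[i] <= out$end[last] + 1L) {
      out$end[last] <- max(out$end[last], spans$end[i])
    } else {
      out <- rbind(out, spans[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Centroid of a structure region
#'
#' Arithmetic mean of the C-alpha coordinates of a region.
#'
#' @param s a `structure_model`.
#' @param chain chain id.
#' @param start,end 1-based sequential positions within the chain
#'   (inclusive).
#' @return numeric length-3 centroid (Angstrom).
#' @export
region_centroid <- function(s, chain, start, end) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  sel <- a$seqpos >= start & a$seqpos <= end
  if (!any(sel)) stop("empty region ", chain, ":", start, "-", end)
  colMeans(as.matrix(a[sel, c("x", "y", "z")]))
}

#' Average distance between APC centroids
#'
#' Mean Euclidean distance over all unordered pairs of centroids.
#'
#' @param centroids numeric matrix with one centroid per row (>= 2 rows).
#' @return mean pairwise distance (Angstrom); 0 iff all centroids coincide.
#' @export
average_apc_distance <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2L) stop("need >= 2 mapped APCs")
  mean(stats::dist(centroids))
}

#' Average pairwise C-alpha distance of a structure
#'
#' Mean Euclidean distance over all unordered C-alpha pairs; the baseline
#' against which APC centroid closeness is judged.
#'
#' @param s a `structure_model`.
#' @param chain optional chain id; default uses all chains of the first
#'   model.
#' @return mean pairwise distance (Angstrom).
#' @export
average_pairwise_ca_distance <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) < 2L) stop("need >= 2 C-alpha atoms")
  mean(stats::dist(as.matrix(a[, c("x", "y", "z")])))
}

#' Map a set of APCs onto a structure and summarize distances
#'
#' Maps every APC (see [map_apc_to_structure]), computes one centroid per
#' APC, and summarizes: when an APC matches several disjoint regions, the
#' region whose centroid is nearest to the other APCs' centroids is kept
#' (alternatives are recorded). Unmapped APCs are excluded from the distance
#' summary with a warning.
#'
#' @param apcs list of `aligned_pattern_cluster` objects.
#' @param s a `structure_model`.
#' @param chain optional chain id for mapping.
#' @param min_partial minimum accepted partial-match length.
#' @return object of class `structure_mapping`: `regions` (per APC),
#'   `centroids` (matrix, one row per mapped APC), `average_apc_distance`,
#'   `average_pairwise_distance`.
#' @export
structure_mapping <- function(apcs, s, chain = NULL, min_partial = 5L) {
  regions <- lapply(apcs, map_apc_to_structure, s = s, chain = chain,
                    min_partial = min_partial)
  names(regions) <- vapply(apcs, `[[`, character(1), "id")
  mapped <- names(regions)[vapply(regions, nrow, integer(1)) > 0L]
  # first pass: centroid over all regions of each APC
  cent_all <- t(vapply(mapped, function(id) {
    r <- regions[[id]]
    colMeans(do.call(rbind, lapply(seq_len(nrow(r)), function(i)
      region_centroid(s, r$chain[i], r$start[i], r$end[i]))))
  }, numeric(3)))
  # second pass: for multi-region APCs keep the region nearest the others
  centroids <- cent_all
  alternatives <- list()
  for (id in mapped) {
    r <- regions[[id]]
    if (nrow(r) < 2L || length(mapped) < 2L) next
    others <- colMeans(cent_all[setdiff(mapped, id), , drop = FALSE])
    cands <- t(vapply(seq_len(nrow(r)), function(i)
      region_centroid(s, r$chain[i], r$start[i], r$end[i]), numeric(3)))
    d <- sqrt(rowSums((cands - matrix(others, nrow(r), 3,
                                      byrow = TRUE))^2))
    keep <- which.min(d)
    centroids[id, ] <- cands[keep, ]
    alternatives[[id]] <- r[-keep, , drop = FALSE]
    regions[[id]] <- r[keep, , drop = FALSE]
  }
  avg_apc <- if (length(mapped) >= 2L) average_apc_distance(centroids) else
    NA_real_
  structure(list(regions = regions,
                 centroids = centroids,
                 mapped = mapped,
                 alternatives = alternatives,
                 average_apc_distance = avg_apc,
                 average_pairwise_distance =
                   average_pairwise_ca_distance(s)),
            class = "structure_mapping")
}

#' @export
print.structure_mapping <- function(x, ...) {
  cat("structure_mapping:", length(x$mapped), "of", length(x$regions),
      "APCs mapped\n")
  cat(sprintf("  average APC centroid distance: %.2f A\n",
              x$average_apc_distance))
  cat(sprintf("  average pairwise C-alpha distance: %.2f A\n",
              x$average_pairwise_distance))
  invisible(x)
}
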