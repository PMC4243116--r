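# 20-letter standard amino-acid alphabet, lexicographic
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a sequence set
#'
#' A `sequence_set` holds an ordered collection of protein sequences from one
#' family, together with the maximum-likelihood background residue
#' frequencies used by the pattern significance statistic. Residues must come
#' from the 20-letter standard amino-acid alphabet; ambiguity codes
#' (B, J, O, U, X, Z) are rejected.
#'
#' @param residues character vector of uppercase amino-acid strings.
#' @param ids character vector of unique sequence identifiers.
#' @param descriptions optional free-text descriptions (default empty).
#' @return An object of class `sequence_set` with elements `id`, `residues`,
#'   `description` and `freq` (named numeric over the alphabet, summing to 1).
#' @export
sequence_set <- function(residues, ids = NULL, descriptions = NULL) {
  if (length(residues) == 0L) stop("no sequences")
  if (is.null(ids)) ids <- paste0("seq", seq_along(residues))
  if (is.null(descriptions)) descriptions <- rep("", length(residues))
  residues <- toupper(as.character(residues))
  ids <- as.character(ids)
  stopifnot(length(residues) == length(ids),
            length(descriptions) == length(residues))
  if (anyDuplicated(ids))
    stop("duplicate identifier: ", ids[duplicated(ids)][1L])
  if (any(!nzchar(residues)))
    stop("empty sequence: ", ids[!nzchar(residues)][1L])
  bad <- validate_residues(residues)
  if (!is.null(bad))
    stop("illegal residue character '", bad$char, "' in sequence '",
         bad$id[1L], "' at position ", bad$pos,
         " (only the 20 standard amino acids are allowed)", call. = FALSE)
  x <- list(id = ids, residues = residues, description = descriptions,
            freq = residue_frequencies(residues))
  class(x) <- "sequence_set"
  x
}

# Returns NULL if clean, else list(id, char, pos) of first offender.
validate_residues <- function(residues) {
  ids <- names(residues)
  for (i in seq_along(residues)) {
    ok <- strsplit(residues[i], "", fixed = TRUE)[[1]] %in% AA_ALPHABET
    if (!all(ok)) {
      pos <- which(!ok)[1L]
      return(list(id = if (is.null(ids)) i else ids[i],
                  char = substr(residues[i], pos, pos), pos = pos))
    }
  }
  NULL
}

#' Background residue frequencies
#'
#' Maximum-likelihood frequency of each standard amino acid over all residues
#' of the set (or of a character vector of sequences). Frequencies sum to 1.
#'
#' @param x a `sequence_set` or character vector of sequences.
#' @return named numeric vector over the 20-letter alphabet.
#' @export
residue_frequencies <- function(x) {
  if (inherits(x, "sequence_set")) x <- x$residues
  chars <- unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  n <- sum(counts)
  f <- as.numeric(counts) / max(n, 1L)
  names(f) <- AA_ALPHABET
  f
}

#' Read a protein family from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a
#' [sequence_set]. The FASTA header up to the first whitespace becomes the
#' sequence id; the remainder becomes the description.
#'
#' @param path path to a FASTA file.
#' @param skip_bad_records if `TRUE`, records containing non-standard residue
#'   letters are dropped with a warning instead of aborting the read.
#' @return a [sequence_set].
#' @export
read_fasta <- function(path, skip_bad_records = FALSE) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in '", path, "'")
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(aa))
  if (anyDuplicated(ids))
    stop("duplicate identifier: ", ids[duplicated(ids)][1L])
  if (skip_bad_records) {
    keep <- rep(TRUE, length(residues))
    for (i in seq_along(residues)) {
      if (!is.null(validate_residues(residues[i]))) keep[i] <- FALSE
    }
    if (!all(keep))
      warning("dropped ", sum(!keep), " record(s) with non-standard residues: ",
              paste(ids[!keep], collapse = ", "))
    residues <- residues[keep]; ids <- ids[keep]
    descriptions <- descriptions[keep]
    if (length(residues) == 0L) stop("no sequences left after filtering")
  }
  sequence_set(residues, ids, descriptions)
}

#' Write a sequence set to FASTA
#'
#' Sequences are written uppercase in input order, wrapped at `width` columns,
#' so that `write_fasta(read_fasta(x))` round-trips normalized input
#' byte-identically.
#'
#' @param x a [sequence_set].
#' @param path output file path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "sequence_set"))
  aa <- Biostrings::AAStringSet(x$residues)
  names(aa) <- ifelse(nzchar(x$description),
                      paste(x$id, x$description), x$id)
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' @export
print.sequence_set <- function(x, ...) {
  lens <- nchar(x$residues)
  cat("sequence_set:", length(x$id), "sequences, lengths",
      min(lens), "-", max(lens), "\n")
  top <- sort(x$freq, decreasing = TRUE)[1:3]
  cat("  top background frequencies:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$id)
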