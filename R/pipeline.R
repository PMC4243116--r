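#' Discover co-occurrence clusters of conserved regions
#'
#' Top-level entry point running the whole pipeline on a protein family:
#' (1) discover statistically significant patterns ([discover_patterns]);
#' (2) group them into Aligned Pattern Clusters ([cluster_patterns]);
#' (3) build the Jaccard co-occurrence graph ([build_graph]); and
#' (4) partition it into Co-occurrence Clusters with the requested
#' algorithm. The fitted object carries every intermediate stage so the
#' clusters can be inspected, re-ranked, or validated against a 3D
#' structure with [structure_mapping].
#'
#' @param seqs a [sequence_set] (see [read_fasta]).
#' @param min_len,max_len,min_occurrence,delta,z_threshold pattern-discovery
#'   settings, see [discover_patterns].
#' @param constraints APC merge constraints, see [apc_constraints].
#' @param algorithm clustering algorithm: `"spectral"` (default),
#'   `"kmedoids"` or `"mst"`.
#' @param k cluster count; `NULL` selects it automatically (eigengap for
#'   spectral, validity-index vote for k-medoids; required for `"mst"`).
#' @param edge_min co-occurrence graph sparsification threshold (default 0).
#' @param seed RNG seed for the k-means restarts of spectral clustering.
#' @return an object of class `apc_cooccurrence` with elements `seqs`,
#'   `patterns`, `apcs`, `graph`, `clustering`, `best_cluster` (label of the
#'   most connected cluster, spectral only, `NA` otherwise) and `call`.
#' @examples
#' fam <- generate_family(synthetic_spec(n_sequences = 40, seed = 7))
#' fit <- apc_cooccurrence(fam$seqs, min_occurrence = 10)
#' fit
#' summary(fit)
#' @export
apc_cooccurrence <- function(seqs, min_len = 5L, max_len = 15L,
                             min_occurrence = 20L, delta = 0.9,
                             z_threshold = 1.96,
                             constraints = apc_constraints(),
                             algorithm = c("spectral", "kmedoids", "mst"),
                             k = NULL, edge_min = 0, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(seqs, "sequence_set"))
  patterns <- discover_patterns(seqs, min_len, max_len, min_occurrence,
                                delta, z_threshold)
  if (nrow(patterns) == 0L)
    stop("no significant patterns; relax min_occurrence or z_threshold")
  apcs <- cluster_patterns(patterns, constraints)
  if (length(apcs) < 2L)
    stop("fewer than 2 APCs; nothing to cluster")
  graph <- build_graph(apcs, edge_min = edge_min)
  clustering <- switch(algorithm,
    spectral = spectral_cluster(graph, k = k, seed = seed),
    kmedoids = kmedoids_cluster(graph, k = k),
    mst = {
      if (is.null(k)) stop("mst clustering needs an explicit k")
      mst_hierarchical_cluster(graph, k = k)
    })
  best <- if (algorithm == "spectral" &&
              any(!is.na(clustering$avg_embedding_distance)))
    select_best_cluster(clustering) else NA_integer_
  structure(list(seqs = seqs, patterns = patterns, apcs = apcs,
                 graph = graph, clustering = clustering,
                 best_cluster = best, call = match.call()),
            class = "apc_cooccurrence")
}

#' @export
print.apc_cooccurrence <- function(x, ...) {
  cat("apc_cooccurrence fit\n")
  cat("  sequences:   ", length(x$seqs$id), "\n")
  cat("  patterns:    ", nrow(x$patterns), "\n")
  cat("  APCs:        ", length(x$apcs), "\n")
  cat("  clustering:  ", x$clustering$algorithm, ", k = ",
      x$clustering$k, "\n", sep = "")
  if (!is.na(x$best_cluster))
    cat("  best cluster:", x$best_cluster, "(lowest mean embedding distance)\n")
  invisible(x)
}

#' @method summary apc_cooccurrence
#' @export
summary.apc_cooccurrence <- function(object, ...) {
  x <- object
  cl <- x$clustering
  cat("Co-occurrence clustering of", length(x$apcs), "APCs (",
      cl$algorithm, ")\n\n")
  for (a in x$apcs) {
    cat(sprintf("%-6s %-20s coverage %3d  cluster %d\n", a$id,
                a$consensus, length(a$coverage),
                cl$assignment[[a$id]]))
  }
  if (!is.null(cl$eigenvalues))
    cat("\neigenvalues:", paste(sprintf("%.3f", cl$eigenvalues),
                                collapse = " "), "\n")
  if (!is.na(x$best_cluster))
    cat("best (most connected) cluster:", x$best_cluster, "\n")
  top <- utils::head(rank_pairs(x$graph), 5)
  cat("\ntop co-occurring APC pairs:\n")
  print(top)
  invisible(x)
}

#' @method plot apc_cooccurrence
#' @export
plot.apc_cooccurrence <- function(x, ...) {
  W <- x$graph$W
  ord <- order(x$clustering$assignment[rownames(W)])
  W <- W[ord, ord]
  n <- nrow(W)
  graphics::image(seq_len(n), seq_len(n), t(W[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "APC co-occurrence (Jaccard)", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(W), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(W)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
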