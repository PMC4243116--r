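#' Degree matrix of a weight matrix
#'
#' Diagonal matrix of row sums `d_i = sum_j W(i, j)`.
#'
#' @param W square, symmetric, non-negative weight matrix.
#' @return diagonal matrix D of the same dimension.
#' @export
degree_matrix <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
  D <- diag(rowSums(W), nrow(W))
  dimnames(D) <- dimnames(W)
  D
}

#' Random-walk graph Laplacian
#'
#' `L_rw = I - D^{-1} W`. Isolated (zero-degree) vertices must be removed
#' before calling: `D^{-1}` is undefined for them.
#'
#' @param W square, symmetric, non-negative weight matrix with no
#'   zero-degree vertex.
#' @return the Laplacian matrix; its eigenvalues are real in [0, 2] and the
#'   multiplicity of 0 equals the number of connected components.
#' @export
laplacian_rw <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  d <- rowSums(W)
  if (any(d == 0)) stop("isolate not removed: vertex with zero degree")
  diag(nrow(W)) - W / d
}

#' Eigengap choice of cluster count
#'
#' `k` is the count of eigenvalues before the largest difference between
#' consecutive ascending eigenvalues; the smallest such index is taken on
#' ties. When all gaps are equal (within machine tolerance) `k = 1` with a
#' warning.
#'
#' @param eigenvalues ascending real eigenvalues (at least 2).
#' @param max_consider consider only the first `max_consider` eigenvalues
#'   (default 10) for stability on small graphs.
#' @return integer k >= 1.
#' @export
eigengap_k <- function(eigenvalues, max_consider = 10L) {
  stopifnot(length(eigenvalues) >= 2L)
  ev <- eigenvalues[seq_len(min(length(eigenvalues), max_consider))]
  gaps <- diff(ev)
  if (length(gaps) > 1L && diff(range(gaps)) < 1e-12) {
    warning("all eigengaps equal; defaulting to k = 1")
    return(1L)
  }
  which.max(gaps)
}

# Connected components of W > 0; returns integer component labels.
graph_components <- function(W) {
  n <- nrow(W)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    stack <- v
    while (length(stack) > 0L) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[u] > 0L) next
      comp[u] <- cur
      stack <- c(stack, which(W[u, ] > 0 & comp == 0L))
    }
  }
  comp
}

# Relabel an assignment so labels are contiguous 1..k, ordered by cluster
# size descending (ties: smallest first member index).
relabel_by_size <- function(assignment) {
  tab <- table(assignment)
  firsts <- vapply(names(tab), function(l) min(which(assignment == l)),
                   integer(1))
  ord <- names(tab)[order(-as.integer(tab), firsts)]
  out <- match(as.character(assignment), ord)
  names(out) <- names(assignment)
  out
}

new_clustering_result <- function(algorithm, assignment, k,
                                  eigenvalues = NULL, embedding = NULL,
                                  avg_embedding_distance = NULL,
                                  objective = NULL) {
  structure(list(algorithm = algorithm, assignment = assignment, k = k,
                 eigenvalues = eigenvalues, embedding = embedding,
                 avg_embedding_distance = avg_embedding_distance,
                 objective = objective),
            class = "cooccurrence_clusters")
}

#' @export
print.cooccurrence_clusters <- function(x, ...) {
  cat("cooccurrence_clusters (", x$algorithm, "): k = ", x$k, "\n", sep = "")
  for (l in sort(unique(x$assignment))) {
    cat("  cluster ", l, ": ",
        paste(names(x$assignment)[x$assignment == l], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Spectral clustering of the co-occurrence graph
#'
#' Random-walk-Laplacian spectral clustering. Isolated vertices (no positive
#' co-occurrence) are split off first, each as its own singleton cluster. On
#' the remainder, `L_rw = I - D^{-1} W` is eigendecomposed; eigenvalues are
#' sorted ascending and, when `k` is not given, chosen by the eigengap
#' heuristic. Vertices are embedded as rows of the first k eigenvector
#' columns (the constant first column included; rows are not re-normalized)
#' and partitioned by k-means with a fixed seed and multiple restarts.
#' Cluster labels are contiguous and ordered by size descending.
#'
#' @param g a `cooccurrence_graph`, or a symmetric non-negative weight
#'   matrix with dimnames.
#' @param k number of clusters on the non-isolated subgraph; `NULL` (default)
#'   selects k by the eigengap heuristic.
#' @param seed RNG seed for the k-means restarts (default 1).
#' @param nstart number of k-means restarts (default 10).
#' @param max_consider eigengap window passed to [eigengap_k].
#' @return a `cooccurrence_clusters` object: `assignment` (named, all
#'   vertices including singletons), `k` (total cluster count), ascending
#'   `eigenvalues`, `embedding`, and per-cluster mean pairwise embedding
#'   distance.
#' @export
spectral_cluster <- function(g, k = NULL, seed = 1L, nstart = 10L,
                             max_consider = 10L) {
  W <- if (inherits(g, "cooccurrence_graph")) g$W else g
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(W)))
  stopifnot(nrow(W) >= 2L)
  deg <- rowSums(W)
  core <- which(deg > 0)
  isolates <- which(deg == 0)

  assignment <- integer(nrow(W))
  names(assignment) <- ids
  eigenvalues <- NULL; embedding <- NULL

  if (length(core) < 2L) {
    # nothing left to decompose: every vertex is its own cluster
    assignment[] <- seq_along(assignment)
    res <- new_clustering_result("spectral", relabel_by_size(assignment),
                                 k = nrow(W))
    return(res)
  }

  Wc <- W[core, core, drop = FALSE]
  L <- laplacian_rw(Wc)
  ed <- eigen(L)
  ord <- order(Re(ed$values))
  eigenvalues <- Re(ed$values)[ord]
  vectors <- Re(ed$vectors)[, ord, drop = FALSE]
  if (is.null(k)) k <- eigengap_k(eigenvalues, max_consider)
  k <- min(k, length(core))
  embedding <- vectors[, seq_len(k), drop = FALSE]
  rownames(embedding) <- ids[core]

  if (k == 1L) {
    core_labels <- rep(1L, length(core))
  } else {
    core_labels <- with_local_seed(seed, {
      stats::kmeans(embedding, centers = k, nstart = nstart,
                    iter.max = 100L)$cluster
    })
  }
  assignment[core] <- core_labels
  if (length(isolates) > 0)
    assignment[isolates] <- max(core_labels) + seq_along(isolates)
  assignment <- relabel_by_size(assignment)

  new_clustering_result("spectral", assignment,
                        k = length(unique(assignment)),
                        eigenvalues = eigenvalues, embedding = embedding,
                        avg_embedding_distance =
                          cluster_embedding_distances(assignment, embedding))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mean pairwise Euclidean distance between embedding rows, per cluster
# (NA for singletons or vertices without embedding rows).
cluster_embedding_distances <- function(assignment, embedding) {
  labels <- sort(unique(assignment))
  out <- vapply(labels, function(l) {
    members <- names(assignment)[assignment == l]
    members <- members[members %in% rownames(embedding)]
    if (length(members) < 2L) return(NA_real_)
    mean(stats::dist(embedding[members, , drop = FALSE]))
  }, numeric(1))
  names(out) <- labels
  out
}

#' Most connected cluster
#'
#' Among clusters with at least two members, returns the label of the one
#' with the lowest mean pairwise eigenvector-embedding distance; singleton
#' clusters are excluded.
#'
#' @param r a spectral `cooccurrence_clusters` result (with embedding).
#' @return integer cluster label.
#' @export
select_best_cluster <- function(r) {
  stopifnot(inherits(r, "cooccurrence_clusters"))
  if (is.null(r$avg_embedding_distance))
    stop("no embedding: best-cluster selection needs a spectral result")
  d <- r$avg_embedding_distance
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no connected cluster with >= 2 members")
  as.integer(names(d)[which.min(d)])
}

#' k-medoids clustering of the co-occurrence graph
#'
#' Similarity-maximizing k-medoids on the Jaccard weights: medoids are
#' initialized to the first vertex of each connected component (extra
#' medoids, when `k` exceeds the component count, are added farthest-first);
#' each vertex joins the medoid with the highest co-occurrence score; a
#' cluster's medoid is updated to the member maximizing the summed score to
#' the other members; assignment and update iterate to a fixed point. When
#' `k` is not given, k runs from the component count to `|V|` and the best k
#' is chosen by majority vote of five internal validity indices (silhouette,
#' Calinski-Harabasz, Davies-Bouldin, Dunn, within/between ratio) computed
#' on the dissimilarity `1 - J`, ties to the smaller k.
#'
#' @param g a `cooccurrence_graph` or weight matrix.
#' @param k number of clusters, or `NULL` for index-based selection.
#' @return a `cooccurrence_clusters` object with `objective` (summed
#'   member-to-medoid similarity) and a `medoids` attribute.
#' @export
kmedoids_cluster <- function(g, k = NULL) {
  W <- if (inherits(g, "cooccurrence_graph")) g$W else g
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(W)))
  stopifnot(nrow(W) >= 2L)
  comp <- graph_components(W)
  n_comp <- max(comp)
  if (is.null(k)) {
    ks <- seq(n_comp, nrow(W))
    if (length(ks) == 1L) return(kmedoids_cluster(g, k = ks))
    fits <- lapply(ks, function(kk) kmedoids_fit(W, ids, comp, kk))
    k_best <- ks[vote_best_k(lapply(fits, `[[`, "assignment"), 1 - W)]
    fit <- fits[[match(k_best, ks)]]
  } else {
    stopifnot(k >= 1L, k <= nrow(W))
    if (k < n_comp)
      warning("k below the component count; distinct components may share ",
              "a medoid only through zero-similarity assignment")
    fit <- kmedoids_fit(W, ids, comp, k)
  }
  assignment <- relabel_by_size(fit$assignment)
  res <- new_clustering_result("kmedoids", assignment,
                               k = length(unique(assignment)),
                               objective = fit$objective)
  attr(res, "medoids") <- fit$medoids
  res
}

kmedoids_fit <- function(W, ids, comp, k) {
  n <- nrow(W)
  obj_for <- function(meds) {
    s <- apply(W[, meds, drop = FALSE], 1L, max)
    s[meds] <- 0
    sum(s)
  }
  # co-occurrence graphs are small; when the medoid-set space is modest the
  # summed-similarity objective is optimized exactly (deterministic, ties to
  # the lexicographically smallest medoid set). Larger graphs fall back to
  # the component-seeded iteration with swap refinement below.
  if (choose(n, k) <= 5000) {
    sets <- utils::combn(n, k)
    objs <- apply(sets, 2L, obj_for)
    medoids <- sets[, which.max(objs)]
    assignment <- integer(n)
    for (v in seq_len(n)) {
      assignment[v] <- if (v %in% medoids) match(v, medoids) else
        which.max(W[v, medoids])
    }
    names(assignment) <- ids
    return(list(assignment = assignment, medoids = ids[medoids],
                objective = max(objs)))
  }
  # first vertex of each component, in component order
  medoids <- vapply(seq_len(max(comp)), function(c) min(which(comp == c)),
                    integer(1))
  if (k < length(medoids)) {
    sizes <- table(comp)
    keep <- order(-as.integer(sizes), seq_along(sizes))[seq_len(k)]
    medoids <- medoids[keep]
  } else if (k > length(medoids)) {
    while (length(medoids) < k) {
      free <- setdiff(seq_len(n), medoids)
      best_sim <- vapply(free, function(v) max(W[v, medoids]), numeric(1))
      medoids <- c(medoids, free[which.min(best_sim)])
    }
  }
  assignment <- rep(NA_integer_, n)
  for (iter in seq_len(100L)) {
    # assign each vertex to its highest-similarity medoid (first on ties,
    # a medoid always owns itself)
    for (v in seq_len(n)) {
      if (v %in% medoids) {
        assignment[v] <- match(v, medoids)
      } else {
        s <- W[v, medoids]
        assignment[v] <- which.max(s)
      }
    }
    # update each medoid to the member maximizing within-cluster similarity
    new_medoids <- medoids
    for (c in seq_along(medoids)) {
      members <- which(assignment == c)
      if (length(members) == 1L) { new_medoids[c] <- members; next }
      score <- vapply(members, function(m)
        sum(W[m, setdiff(members, m)]), numeric(1))
      new_medoids[c] <- members[which.max(score)]
    }
    if (identical(new_medoids, medoids)) break
    medoids <- new_medoids
  }
  # PAM-style swap phase: replace one medoid by a non-medoid whenever the
  # greedy-assignment objective improves; deterministic (best swap first)
  objective <- obj_for(medoids)
  repeat {
    best_gain <- 0; best_swap <- NULL
    for (c in seq_along(medoids)) {
      for (v in setdiff(seq_len(n), medoids)) {
        cand <- medoids; cand[c] <- v
        gain <- obj_for(cand) - objective
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best_swap <- cand
        }
      }
    }
    if (is.null(best_swap)) break
    medoids <- best_swap
    objective <- objective + best_gain
  }
  for (v in seq_len(n)) {
    assignment[v] <- if (v %in% medoids) match(v, medoids) else
      which.max(W[v, medoids])
  }
  names(assignment) <- ids
  list(assignment = assignment, medoids = ids[medoids],
       objective = objective)
}

# Majority vote over five internal validity indices; returns the index into
# `assignments` of the winning k (ties to the earliest, i.e. smallest k).
vote_best_k <- function(assignments, D) {
  idx <- vapply(assignments, function(a) validity_indices(a, D), numeric(5))
  # rows: silhouette(max), CH(max), DB(min), Dunn(max), wb_ratio(min)
  pick <- function(vals, maximize) {
    vals[is.na(vals)] <- if (maximize) -Inf else Inf
    if (maximize) which.max(vals) else which.min(vals)
  }
  votes <- c(pick(idx[1L, ], TRUE), pick(idx[2L, ], TRUE),
             pick(idx[3L, ], FALSE), pick(idx[4L, ], TRUE),
             pick(idx[5L, ], FALSE))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

# Internal validity indices on a dissimilarity matrix.
validity_indices <- function(assignment, D) {
  n <- length(assignment)
  labels <- unique(assignment)
  k <- length(labels)
  if (k < 2L || k >= n)
    return(c(sil = NA, ch = NA, db = NA, dunn = NA, wb = NA))
  # silhouette (singletons contribute 0, the usual convention)
  sil <- vapply(seq_len(n), function(i) {
    own <- which(assignment == assignment[i] & seq_len(n) != i)
    if (length(own) == 0L) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(labels, assignment[i]), function(l)
      mean(D[i, assignment == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  within <- unlist(lapply(labels, function(l) {
    m <- which(assignment == l)
    if (length(m) < 2L) return(NULL)
    D[m, m][upper.tri(D[m, m])]
  }))
  between <- unlist(lapply(seq_along(labels)[-1L], function(a)
    unlist(lapply(seq_len(a - 1L), function(b)
      as.vector(D[assignment == labels[a], assignment == labels[b]])))))
  wb <- if (length(within) == 0L || length(between) == 0L) NA else
    mean(within) / mean(between)
  dunn <- if (length(within) == 0L || length(between) == 0L) NA else
    min(between) / max(within)
  # CH / DB via medoid-style representatives on the dissimilarity
  reps <- vapply(labels, function(l) {
    m <- which(assignment == l)
    m[which.min(vapply(m, function(i) sum(D[i, m]), numeric(1)))]
  }, integer(1))
  wss <- sum(vapply(seq_len(n), function(i)
    D[i, reps[match(assignment[i], labels)]]^2, numeric(1)))
  grand <- which.min(vapply(seq_len(n), function(i) sum(D[i, ]), numeric(1)))
  bss <- sum(vapply(seq_len(n), function(i) D[i, grand]^2, numeric(1))) - wss
  ch <- if (wss <= 0) NA else (bss / (k - 1)) / (wss / (n - k))
  sbar <- vapply(seq_along(labels), function(a) {
    m <- which(assignment == labels[a])
    mean(D[m, reps[a]])
  }, numeric(1))
  db <- mean(vapply(seq_along(labels), function(a) {
    others <- setdiff(seq_along(labels), a)
    max(vapply(others, function(b) {
      d_ab <- D[reps[a], reps[b]]
      if (d_ab == 0) return(Inf)
      (sbar[a] + sbar[b]) / d_ab
    }, numeric(1)))
  }, numeric(1)))
  c(sil = mean(sil), ch = ch, db = db, dunn = dunn, wb = wb)
}

#' MST hierarchical clustering of the co-occurrence graph
#'
#' Builds a maximum spanning tree per connected component with Prim's
#' algorithm, then repeatedly cuts the currently minimal-weight tree edge
#' until `k` clusters exist. Ties (equal-weight edges) are broken by
#' lexicographic edge id so the result is deterministic.
#'
#' @param g a `cooccurrence_graph` or weight matrix.
#' @param k desired cluster count; must lie between the component count and
#'   `|V|`.
#' @return a `cooccurrence_clusters` object; the forest is attached as a
#'   `tree_edges` attribute (data.frame `from`, `to`, `weight`).
#' @export
mst_hierarchical_cluster <- function(g, k) {
  W <- if (inherits(g, "cooccurrence_graph")) g$W else g
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(W)))
  n <- nrow(W)
  stopifnot(n >= 2L, k >= 1L, k <= n)
  comp <- graph_components(W)
  n_comp <- max(comp)
  if (k < n_comp)
    stop("k = ", k, " not achievable: graph has ", n_comp,
         " components")
  edges <- maximum_spanning_forest(W, comp)
  n_cut <- k - n_comp
  if (n_cut > nrow(edges))
    stop("k = ", k, " not achievable: forest has only ", nrow(edges),
         " edges")
  if (n_cut > 0) {
    ord <- order(edges$weight, ids[edges$from], ids[edges$to])
    edges <- edges[-ord[seq_len(n_cut)], , drop = FALSE]
  }
  A <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    A[cbind(edges$from, edges$to)] <- 1
    A[cbind(edges$to, edges$from)] <- 1
  }
  assignment <- graph_components(A)
  names(assignment) <- ids
  assignment <- relabel_by_size(assignment)
  res <- new_clustering_result("mst", assignment,
                               k = length(unique(assignment)))
  attr(res, "tree_edges") <- data.frame(from = ids[edges$from],
                                        to = ids[edges$to],
                                        weight = edges$weight,
                                        stringsAsFactors = FALSE)
  res
}

# Prim maximum spanning forest; deterministic: each component grows from its
# smallest vertex index, ties on weight broken by lexicographic (new vertex
# id, attaching vertex id).
maximum_spanning_forest <- function(W, comp = graph_components(W)) {
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(W)))
  from <- integer(); to <- integer(); weight <- numeric()
  for (c in seq_len(max(comp))) {
    verts <- which(comp == c)
    if (length(verts) < 2L) next
    in_tree <- verts[1L]
    remaining <- setdiff(verts, in_tree)
    while (length(remaining) > 0L) {
      best <- NULL
      for (v in remaining) {
        for (u in in_tree) {
          if (W[u, v] <= 0) next
          better <- is.null(best) || W[u, v] > best$w ||
            (W[u, v] == best$w && (ids[v] < ids[best$v] ||
               (ids[v] == ids[best$v] && ids[u] < ids[best$u])))
          if (better) best <- list(u = u, v = v, w = W[u, v])
        }
      }
      from <- c(from, best$u); to <- c(to, best$v)
      weight <- c(weight, best$w)
      in_tree <- c(in_tree, best$v)
      remaining <- setdiff(remaining, best$v)
    }
  }
  data.frame(from = from, to = to, weight = weight)
}
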