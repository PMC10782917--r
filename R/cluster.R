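#' Gaussian-mixture clustering of embeddings
#'
#' Model-based clustering used when the number of spatial domains is known:
#' fits a k-component Gaussian mixture to the latent embeddings with
#' `mclust::Mclust` (EM over its covariance-model family, best BIC kept) and
#' assigns each spot to its maximum-posterior component.
#'
#' @param E an [embedding_matrix()] or numeric matrix.
#' @param k number of domains (2 <= k <= n_spots).
#' @param seed integer seed (EM initialisation is deterministic given it).
#' @return A [domain_labels()] with `K = k`, `refined = FALSE`.
#' @export
gmm_cluster <- function(E, k, seed = 1L) {
  v <- if (inherits(E, "embedding_matrix")) E$values else as.matrix(E)
  ids <- if (inherits(E, "embedding_matrix")) E$spot_ids else rownames(v)
  n <- nrow(v)
  if (k < 2 || k > n) stop("k must lie in [2, n_spots]")
  if (k == n) {
    return(domain_labels(seq_len(n), K = n, refined = FALSE, spot_ids = ids))
  }
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller's scope
  fitted <- tryCatch(
    mclust::Mclust(v, G = k, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fitted)) {   # restrict model family before giving up
    for (mn in c("VVV", "EEE", "EII")) {
      fitted <- tryCatch(mclust::Mclust(v, G = k, modelNames = mn,
                                        verbose = FALSE),
                         error = function(e) NULL)
      if (!is.null(fitted)) break
    }
  }
  if (is.null(fitted)) stop("EM failed for all attempted covariance models")
  domain_labels(as.integer(fitted$classification), K = k, refined = FALSE,
                spot_ids = ids)
}

#' Louvain clustering of embeddings
#'
#' Used when the domain count is unknown: builds a k-nearest-neighbour graph
#' on the embeddings (Euclidean, undirected union of directed kNN edges) and
#' runs Louvain modularity optimisation at the given resolution. The number
#' of domains is whatever the partition yields; raising `resolution` or
#' lowering `n_neighbors` increases it.
#'
#' @param E an [embedding_matrix()] or numeric matrix.
#' @param resolution Louvain resolution parameter (default 1.2).
#' @param n_neighbors neighbours per spot in the graph (default 15).
#' @param seed integer seed.
#' @return A [domain_labels()].
#' @export
louvain_cluster <- function(E, resolution = 1.2, n_neighbors = 15L, seed = 1L) {
  v <- if (inherits(E, "embedding_matrix")) E$values else as.matrix(E)
  ids <- if (inherits(E, "embedding_matrix")) E$spot_ids else rownames(v)
  n <- nrow(v)
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  n_neighbors <- min(n_neighbors, n - 1L)
  nn <- .knn_indices(v, n_neighbors)
  edges <- rbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(t(edges), directed = FALSE))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  domain_labels(as.integer(igraph::membership(comm)), refined = FALSE,
                spot_ids = ids)
}

# k nearest neighbours (self excluded) by Euclidean distance; n x k index matrix
.knn_indices <- function(v, k) {
  D <- pairwise_distance(v)
  diag(D) <- Inf
  t(apply(D, 1, function(r) order(r)[seq_len(k)]))
}

#' Spatial majority-vote refinement of domain labels
#'
#' One simultaneous pass over all spots: each spot's `k_neighbors` nearest
#' spatial neighbours are inspected under the *pre-pass* labels, and if some
#' single domain different from the spot's own is held by strictly more than
#' half of them, the spot is relabeled to that majority domain. Ties and
#' mere pluralities leave the label unchanged. `iterate = TRUE` repeats the
#' pass until no label changes (at most `n_spots` passes).
#'
#' @param labels a [domain_labels()].
#' @param coords a [spot_coordinates()] aligned with `labels`.
#' @param k_neighbors neighbourhood size (default 6, the hexagonal-lattice
#'   neighbour count of standard spotted arrays).
#' @param iterate repeat until convergence instead of a single pass.
#' @return A [domain_labels()] with `refined = TRUE`.
#' @export
refine_labels <- function(labels, coords, k_neighbors = 6L, iterate = FALSE) {
  stopifnot(inherits(labels, "domain_labels"),
            inherits(coords, "spot_coordinates"))
  n <- length(labels$labels)
  if (nrow(coords$positions) != n) stop("labels and coords must be aligned")
  if (k_neighbors >= n) stop("k_neighbors must be smaller than n_spots")
  nn <- .knn_indices(coords$positions, k_neighbors)
  cur <- labels$labels
  for (pass in seq_len(if (iterate) n else 1L)) {
    nl <- matrix(cur[nn], nrow = n)
    nxt <- vapply(seq_len(n), function(i) {
      tab <- tabulate(nl[i, ], nbins = labels$K)
      top <- which.max(tab)
      if (top != cur[i] && tab[top] > k_neighbors / 2) top else cur[i]
    }, integer(1))
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  domain_labels(cur, K = labels$K, refined = TRUE, spot_ids = labels$spot_ids)
}
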