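#' k-nearest-neighbour graph of a distance matrix
#'
#' Links every node to its `k` smallest-distance neighbours and
#' symmetrizes the edge set by union (an edge exists if either endpoint
#' lists the other).  Edge lengths are the input distances `d`; edge
#' affinities `w = 1/d` are carried alongside.  Distance ties in the
#' neighbour ranking are broken by the smaller node index.
#'
#' @param D A [dist_matrix()] (typically kind `"pseudo"`) or plain matrix.
#' @param k Number of neighbours, `1 <= k <= M - 1`.
#' @param on_fragmented What to do when the union graph is disconnected:
#'   `"error"` (default) raises a fragmentation error naming the
#'   components -- the caller may retry with a larger `k`; `"largest"`
#'   keeps the largest connected component (loud warning).
#' @return Object of class `neighbor_graph`: fields `m`, `k`, `edges`
#'   (data frame `i`, `j`, `d`, `w` with `i < j`), `connected`, `labels`,
#'   `kept` (node indices retained).
#' @export
knn_graph <- function(D, k, on_fragmented = c("error", "largest")) {
  on_fragmented <- match.arg(on_fragmented)
  dm <- dist_entries(D)
  m <- nrow(dm)
  k <- as.integer(k)
  if (k < 1L || k > m - 1L)
    abort_embedfcn("k must be in 1..M-1", "embedfcn_validation_error")
  labels <- rownames(dm) %||% roi_labels(m)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    ord <- order(dm[i, ])          # stable: ties go to the smaller index
    nb <- setdiff(ord, i)[seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)              # union symmetrization
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  connected <- comp$no == 1L
  kept <- seq_len(m)
  if (!connected) {
    sizes <- sort(comp$csize, decreasing = TRUE)
    if (on_fragmented == "error")
      abort_embedfcn(
        sprintf("k-NN graph fragmented at k = %d: %d components of sizes %s",
                k, comp$no, paste(sizes, collapse = ", ")),
        "embedfcn_fragmentation_error")
    keep_comp <- which.max(comp$csize)
    kept <- which(comp$membership == keep_comp)
    warning(sprintf(
      "k-NN graph fragmented at k = %d; keeping largest component (%d of %d nodes)",
      k, length(kept), m), call. = FALSE)
    adj <- adj[kept, kept, drop = FALSE]
    dm <- dm[kept, kept, drop = FALSE]
    labels <- labels[kept]
    m <- length(kept)
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  d <- dm[idx]
  if (any(d <= 0))
    d[d <= 0] <- .Machine$double.eps   # duplicate points: keep lengths positive
  edges <- data.frame(i = idx[, 1L], j = idx[, 2L], d = d, w = 1 / d)
  structure(list(m = m, k = k, edges = edges, connected = TRUE,
                 labels = labels, kept = kept),
            class = "neighbor_graph")
}

# igraph view of a neighbor_graph or fcn, with edge attribute d (length)
as_igraph_lengths <- function(g) {
  ig <- igraph::graph_from_edgelist(as.matrix(g$edges[, c("i", "j")]),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$m - igraph::vcount(ig)))
  igraph::E(ig)$d <- g$edges$d
  igraph::E(ig)$w <- g$edges$w
  ig
}

#' Geodesic (shortest-path) distance matrix of a neighbour graph
#'
#' All-pairs shortest paths over the graph's edge lengths `d` (Dijkstra);
#' approximates distance along the data manifold.
#'
#' @param g A [knn_graph()] result; must be connected.
#' @return A [dist_matrix()] of kind `"geodesic"`.
#' @export
geodesic_matrix <- function(g) {
  if (!inherits(g, "neighbor_graph"))
    abort_embedfcn("g must be a neighbor_graph", "embedfcn_validation_error")
  ig <- as_igraph_lengths(g)
  dg <- igraph::distances(ig, weights = igraph::E(ig)$d, algorithm = "dijkstra")
  if (any(!is.finite(dg)))
    abort_embedfcn("graph is disconnected; geodesic distances undefined",
                   "embedfcn_fragmentation_error")
  dimnames(dg) <- list(g$labels, g$labels)
  dist_matrix(dg, "geodesic")
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates
#' scaled by the square roots of the positive eigenvalues.  Geodesic
#' matrices are generally non-Euclidean, so negative eigenvalues can
#' occur; they are excluded from the coordinates and their magnitudes
#' recorded.  If fewer than `p_max` eigenvalues are positive the
#' coordinates are truncated and `p_used` records the usable dimension
#' count.
#'
#' @param Dg A [dist_matrix()] (kind `"geodesic"`, or `"pseudo"` /
#'   `"embedded"` for direct use) or plain matrix.
#' @param p_max Maximum embedding dimension to retain, default 15
#'   (diagnostic range); capped at `M - 1`.
#' @return Object of class `embedding_result`: `eigenvalues` (all M,
#'   descending), `coordinates` (M x `p_used`), `residual_variances`
#'   (length `p_used`), `p_used`, `negative_magnitude` (largest |negative
#'   eigenvalue|), `labels`, `k_used` (filled by [isomap_embed()]).
#' @export
classical_mds <- function(Dg, p_max = 15L) {
  dm <- dist_entries(Dg)
  m <- nrow(dm)
  p_max <- min(as.integer(p_max), m - 1L)
  if (p_max < 1L)
    abort_embedfcn("p_max must be >= 1", "embedfcn_validation_error")
  b <- -0.5 * dm^2
  b <- sweep(b, 1L, rowMeans(b))
  b <- sweep(b, 2L, colMeans(b))
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)       # eigenvalues already descending
  lam <- e$values
  tol <- max(abs(lam)) * 1e-12
  npos <- sum(lam > tol)
  p_used <- min(p_max, npos)
  coords <- e$vectors[, seq_len(p_used), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(p_used)]), p_used)
  rownames(coords) <- rownames(dm)
  rv <- vapply(seq_len(p_used), function(p)
    residual_variance(dm, coords[, seq_len(p), drop = FALSE]), numeric(1L))
  structure(list(
    eigenvalues = lam,
    coordinates = coords,
    residual_variances = rv,
    p_used = p_used,
    negative_magnitude = if (any(lam < 0)) max(abs(lam[lam < 0])) else 0,
    labels = rownames(dm) %||% roi_labels(m),
    k_used = NA_integer_
  ), class = "embedding_result")
}

#' Residual variance of an embedding
#'
#' `1 - r^2`, where `r` is the Pearson correlation between the
#' upper-triangle vectorizations of the reference distance matrix and the
#' Euclidean distance matrix of the coordinates.  Zero means the embedding
#' reproduces the distances perfectly.
#'
#' @param Dg Reference distance matrix ([dist_matrix()] or plain matrix).
#' @param coords Numeric M x p coordinate matrix.
#' @return Residual variance in `[0, 1]`.
#' @export
residual_variance <- function(Dg, coords) {
  dm <- dist_entries(Dg)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(dm))
    abort_embedfcn("coords must have one row per node", "embedfcn_validation_error")
  ut <- upper.tri(dm)
  dy <- as.matrix(stats::dist(coords))
  a <- dm[ut]; b <- dy[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort_embedfcn("zero variance in distance vectorization; residual variance undefined",
                   "embedfcn_degenerate_error")
  max(0, 1 - stats::cor(a, b)^2)
}

#' ISOMAP embedding of a pseudo-distance matrix
#'
#' Convenience wrapper chaining [knn_graph()], [geodesic_matrix()] and
#' [classical_mds()].
#'
#' @inheritParams knn_graph
#' @inheritParams classical_mds
#' @return An `embedding_result` with `k_used` set.
#' @export
isomap_embed <- function(D, k, p_max = 15L, on_fragmented = c("error", "largest")) {
  g <- knn_graph(D, k, on_fragmented)
  res <- classical_mds(geodesic_matrix(g), p_max)
  res$k_used <- g$k
  res
}

#' Euclidean distance matrix of the first p embedded dimensions
#'
#' @param res An `embedding_result`.
#' @param p Embedding dimension, `1 <= p <= res$p_used`.
#' @return A [dist_matrix()] of kind `"embedded"`.
#' @export
embedded_distance_matrix <- function(res, p) {
  if (!inherits(res, "embedding_result"))
    abort_embedfcn("res must be an embedding_result", "embedfcn_validation_error")
  p <- as.integer(p)
  if (p < 1L || p > res$p_used)
    abort_embedfcn(sprintf("p = %d exceeds the usable embedding dimensions (%d)",
                           p, res$p_used),
                   "embedfcn_validation_error")
  dm <- as.matrix(stats::dist(res$coordinates[, seq_len(p), drop = FALSE]))
  dimnames(dm) <- list(res$labels, res$labels)
  dist_matrix(dm, "embedded")
}

#' Cohort-level eigengap and residual-variance diagnostics
#'
#' For each subject computes the pairwise differences of the `n_top`
#' largest MDS eigenvalues (padding with zeros when fewer are available)
#' and averages the difference sequences across subjects; also averages
#' the residual-variance-per-dimension curves.  A gap concentrated in the
#' first few differences signals the intrinsic dimension of the cohort's
#' connectivity manifolds.
#'
#' @param results List of `embedding_result` objects.
#' @param n_top Number of leading eigenvalues to compare, default 15.
#' @return List with `eigengap` (length `n_top - 1` mean difference
#'   sequence) and `residual_variance` (mean curve over dimensions
#'   `1..max p_used`, `NA` beyond a subject's usable range is skipped).
#' @export
eigengap_profile <- function(results, n_top = 15L) {
  if (length(results) == 0L)
    abort_embedfcn("empty list of embedding results", "embedfcn_validation_error")
  n_top <- as.integer(n_top)
  diffs <- vapply(results, function(r) {
    lam <- r$eigenvalues
    if (length(lam) < n_top) lam <- c(lam, rep(0, n_top - length(lam)))
    -diff(lam[seq_len(n_top)])
  }, numeric(n_top - 1L))
  pmax_all <- max(vapply(results, function(r) r$p_used, integer(1L)))
  rv <- vapply(seq_len(pmax_all), function(p) {
    vals <- vapply(results, function(r)
      if (r$p_used >= p) r$residual_variances[p] else NA_real_, numeric(1L))
    mean(vals, na.rm = TRUE)
  }, numeric(1L))
  list(eigengap = rowMeans(as.matrix(diffs)), residual_variance = rv)
}
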