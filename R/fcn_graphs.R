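#' Proportional thresholding of a distance matrix into an FCN
#'
#' Keeps the `round(pt/100 * M(M-1)/2)` smallest-distance node pairs (the
#' strongest connections), so graph density is equal across subjects.
#' Rounding is half-up; ties at the quota boundary are broken by
#' lexicographic `(i, j)` order.  The graph stays weighted: each retained
#' edge carries its distance `d` and affinity `w = 1/d`.
#'
#' @param D A [dist_matrix()] (kind `"pseudo"` or `"embedded"`) or plain
#'   symmetric matrix.
#' @param pt Percentage of pairs retained, in `(0, 100]`.
#' @return Object of class `fcn`: fields `m`, `edges` (data frame `i`,
#'   `j`, `d`, `w`), `pt_level`, `source_kind`, `labels`.
#' @export
proportional_threshold <- function(D, pt) {
  if (!is.numeric(pt) || length(pt) != 1L || is.na(pt) || pt <= 0 || pt > 100)
    abort_embedfcn("pt must be a percentage in (0, 100]", "embedfcn_validation_error")
  dm <- dist_entries(D)
  kind <- if (inherits(D, "fcn_dist")) D$kind else "pseudo"
  m <- nrow(dm)
  labels <- rownames(dm) %||% roi_labels(m)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  d <- dm[idx]
  n_pairs <- m * (m - 1L) / 2
  quota <- round_half_up(pt / 100 * n_pairs)
  ord <- order(d, idx[, 1L], idx[, 2L])[seq_len(quota)]
  dd <- d[ord]
  dd[dd <= 0] <- .Machine$double.eps
  edges <- data.frame(i = idx[ord, 1L], j = idx[ord, 2L], d = dd, w = 1 / dd)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(m = m, edges = edges, pt_level = pt, source_kind = kind,
                 labels = labels),
            class = "fcn")
}

#' @export
print.fcn <- function(x, ...) {
  cat(sprintf("<fcn> %d nodes, %d edges (PT = %g%%, source = %s)\n",
              x$m, nrow(x$edges), x$pt_level, x$source_kind))
  invisible(x)
}

# dense helper matrices: affinity W (0 off-edge), adjacency A
fcn_weight_matrix <- function(f) {
  w <- matrix(0, f$m, f$m, dimnames = list(f$labels, f$labels))
  w[cbind(f$edges$i, f$edges$j)] <- f$edges$w
  w[cbind(f$edges$j, f$edges$i)] <- f$edges$w
  w
}

fcn_adjacency <- function(f) {
  a <- matrix(0, f$m, f$m)
  a[cbind(f$edges$i, f$edges$j)] <- 1
  a[cbind(f$edges$j, f$edges$i)] <- 1
  a
}

#' Node strength
#'
#' Sum of the affinity weights `w = 1/d` of a node's incident edges.
#' Isolated nodes have strength 0.
#'
#' @param f An [proportional_threshold()] graph.
#' @return Named numeric vector of length `m`.
#' @export
strength <- function(f) rowSums(fcn_weight_matrix(f))

#' Weighted local clustering coefficient
#'
#' `c_i = 1 / (s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 * a_ij a_ih a_jh`:
#' for every triangle through `i` the mean affinity of the two edges at
#' `i`, normalised by strength and degree.  Nodes of degree < 2 get 0.
#'
#' @inheritParams strength
#' @return Named numeric vector of length `m`.
#' @export
local_clustering <- function(f) {
  w <- fcn_weight_matrix(f)
  a <- fcn_adjacency(f)
  k <- rowSums(a)
  s <- rowSums(w)
  num <- rowSums(w * (a %*% a))     # sum_j w_ij * #{h: i~h, j~h}
  c_i <- ifelse(k >= 2, num / (s * (k - 1)), 0)
  stats::setNames(c_i, f$labels)
}

# global efficiency of a length-weighted igraph (unreachable pairs -> 0)
global_efficiency_lengths <- function(ig, lengths) {
  n <- igraph::vcount(ig)
  if (n < 2L) return(0)
  dg <- igraph::distances(ig, weights = lengths)
  inv <- 1 / dg
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbours, where efficiency averages reciprocal shortest-path lengths
#' (edge lengths `d`; unreachable pairs contribute 0).  Nodes of degree
#' < 2 get 0.
#'
#' @inheritParams strength
#' @return Named numeric vector of length `m`.
#' @export
local_efficiency <- function(f) {
  len <- matrix(Inf, f$m, f$m)
  len[cbind(f$edges$i, f$edges$j)] <- f$edges$d
  len[cbind(f$edges$j, f$edges$i)] <- f$edges$d
  adj <- is.finite(len)
  el <- vapply(seq_len(f$m), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    sub <- len[nb, nb, drop = FALSE]
    diag(sub) <- 0
    # all-pairs shortest paths by min-plus relaxation over intermediates
    for (mm in seq_len(k))
      sub <- pmin(sub, outer(sub[, mm], sub[mm, ], "+"))
    inv <- 1 / sub
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1L))
  stats::setNames(el, f$labels)
}

#' Weighted betweenness centrality
#'
#' Fraction of shortest paths (by edge lengths `d`) between all other node
#' pairs that pass through each node; endpoints excluded, unreachable
#' pairs skipped.
#'
#' @inheritParams strength
#' @return Named numeric vector of length `m`.
#' @export
betweenness <- function(f) {
  ig <- as_igraph_lengths(f)
  b <- igraph::betweenness(ig, weights = igraph::E(ig)$d, directed = FALSE)
  stats::setNames(as.numeric(b), f$labels)
}

#' Louvain community detection with restarts
#'
#' Runs the Louvain modularity-maximization algorithm on the affinity
#' weights `w`, `restarts` times under a derived seed each, and returns
#' the partition with the highest modularity.  Deterministic given
#' `seed`.
#'
#' @inheritParams strength
#' @param seed Integer seed.
#' @param restarts Number of seeded restarts, default 10.
#' @return Integer vector: module id per node (isolated nodes get their
#'   own module).
#' @export
louvain_communities <- function(f, seed, restarts = 10L) {
  if (nrow(f$edges) == 0L)
    abort_embedfcn("graph has no edges; no community structure",
                   "embedfcn_validation_error")
  ig <- as_igraph_lengths(f)
  w <- igraph::E(ig)$w
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    memb <- withr::with_seed(as.integer(seed) + r, {
      igraph::membership(igraph::cluster_louvain(ig, weights = w))
    })
    q <- igraph::modularity(ig, memb, weights = w)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  stats::setNames(as.integer(best), f$labels)
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_m (k_i(m) / k_i)^2` over modules `m`, with binary
#' degrees `k`.  A node whose links all stay inside its own module has
#' PC 0; a node spreading evenly across modules approaches 1.  Isolated
#' nodes get 0.
#'
#' @inheritParams strength
#' @param partition Integer module id per node (e.g. from
#'   [louvain_communities()]).
#' @return Named numeric vector in `[0, 1)`.
#' @export
participation_coefficient <- function(f, partition) {
  if (length(partition) != f$m)
    abort_embedfcn("partition must cover all nodes", "embedfcn_validation_error")
  a <- fcn_adjacency(f)
  k <- rowSums(a)
  mods <- sort(unique(partition))
  km2 <- rowSums(vapply(mods, function(mm)
    rowSums(a[, partition == mm, drop = FALSE])^2, numeric(f$m)))
  pc <- ifelse(k > 0, 1 - km2 / k^2, 0)
  stats::setNames(pc, f$labels)
}

# measure-major feature order; prefixes follow the usual shorthand
# St = strength, Lef = local efficiency, Lc = local clustering,
# Bc = betweenness centrality, Pc = participation coefficient
measure_prefixes <- c(St = "strength", Lef = "efficiency", Lc = "clustering",
                      Bc = "betweenness", Pc = "participation")

#' Feature names for an M-node graph
#'
#' @param labels ROI label vector.
#' @return Character vector of length `5 * M` in measure-major order.
#' @export
feature_names <- function(labels) {
  as.vector(vapply(names(measure_prefixes),
                   function(p) paste0(p, ":", labels),
                   character(length(labels))))
}

#' Per-subject node-measure feature vector
#'
#' Computes all five local measures (participation via
#' [louvain_communities()] under the given seed) and flattens them in
#' measure-major, node-minor order: strength, local efficiency, local
#' clustering, betweenness, participation.  Length `5 * m` (420 for the
#' 84-ROI parcellation).
#'
#' @inheritParams strength
#' @param seed Integer seed for the community detection.
#' @param restarts Louvain restarts, default 10.
#' @return Named numeric vector of length `5 * m`.
#' @export
feature_vector <- function(f, seed, restarts = 10L) {
  part <- louvain_communities(f, seed, restarts)
  v <- c(strength(f), local_efficiency(f), local_clustering(f),
         betweenness(f), participation_coefficient(f, part))
  stats::setNames(v, feature_names(f$labels))
}
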