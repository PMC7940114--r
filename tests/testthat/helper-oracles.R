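# Independent brute-force oracles used across the suite.  Everything here
# is deliberately naive (double loops, exhaustive enumeration) and shares
# no code with the package implementation paths it checks.

# Eq-style lagged cross-correlation by direct summation
oracle_ccf <- function(x, y, l) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(sum((x - mx)^2) / n)
  sy <- sqrt(sum((y - my)^2) / n)
  s <- 0
  for (t in seq_len(n)) {
    tl <- t + l
    if (tl >= 1 && tl <= n) s <- s + (x[tl] - mx) * (y[t] - my)
  }
  s / (n * sx * sy)
}

# Floyd–Warshall all-pairs shortest paths on a length matrix (Inf = no edge)
oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# dense weight/length/adjacency matrices from an fcn object
fcn_mats <- function(f) {
  m <- f$m
  W <- matrix(0, m, m); L <- matrix(Inf, m, m); A <- matrix(0, m, m)
  for (r in seq_len(nrow(f$edges))) {
    i <- f$edges$i[r]; j <- f$edges$j[r]
    W[i, j] <- W[j, i] <- f$edges$w[r]
    L[i, j] <- L[j, i] <- f$edges$d[r]
    A[i, j] <- A[j, i] <- 1
  }
  list(W = W, L = L, A = A)
}

oracle_strength <- function(f) rowSums(fcn_mats(f)$W)

oracle_clustering <- function(f) {
  mats <- fcn_mats(f)
  m <- f$m
  out <- numeric(m)
  for (i in seq_len(m)) {
    k <- sum(mats$A[i, ])
    s <- sum(mats$W[i, ])
    if (k < 2) next
    acc <- 0
    for (j in seq_len(m)) for (h in seq_len(m)) {
      acc <- acc + (mats$W[i, j] + mats$W[i, h]) / 2 *
        mats$A[i, j] * mats$A[i, h] * mats$A[j, h]
    }
    out[i] <- acc / (s * (k - 1))
  }
  out
}

oracle_local_efficiency <- function(f) {
  mats <- fcn_mats(f)
  m <- f$m
  out <- numeric(m)
  for (i in seq_len(m)) {
    nb <- which(mats$A[i, ] > 0)
    n <- length(nb)
    if (n < 2) next
    sub <- mats$L[nb, nb, drop = FALSE]
    dg <- oracle_floyd_warshall(sub)
    inv <- 1 / dg
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    out[i] <- sum(inv) / (n * (n - 1))
  }
  out
}

# betweenness by enumerating all shortest paths (branch-and-bound over
# simple paths no longer than the shortest distance)
oracle_betweenness <- function(f, tol = 1e-10) {
  mats <- fcn_mats(f)
  m <- f$m
  dg <- oracle_floyd_warshall(mats$L)
  count_paths <- function(s, t) {
    # returns c(total paths, through-counts per node)
    through <- numeric(m)
    total <- 0
    recurse <- function(node, len, visited) {
      if (node == t) {
        total <<- total + 1
        inner <- setdiff(visited, c(s, t))
        through[inner] <<- through[inner] + 1
        return(invisible())
      }
      for (nx in which(is.finite(mats$L[node, ]))) {
        if (nx %in% visited) next
        nl <- len + mats$L[node, nx]
        if (nl > dg[s, t] + tol) next
        if (nl + dg[nx, t] > dg[s, t] + tol) next
        recurse(nx, nl, c(visited, nx))
      }
    }
    recurse(s, 0, s)
    list(total = total, through = through)
  }
  b <- numeric(m)
  for (s in seq_len(m - 1)) for (t in (s + 1):m) {
    if (!is.finite(dg[s, t])) next
    cp <- count_paths(s, t)
    if (cp$total > 0) b <- b + cp$through / cp$total
  }
  b
}

oracle_participation <- function(f, partition) {
  mats <- fcn_mats(f)
  m <- f$m
  out <- numeric(m)
  for (i in seq_len(m)) {
    k <- sum(mats$A[i, ])
    if (k == 0) next
    acc <- 0
    for (mm in unique(partition)) {
      km <- sum(mats$A[i, partition == mm])
      acc <- acc + (km / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# random weighted graph as an fcn object: n nodes, each pair linked with
# probability p_edge, lengths uniform in (0.2, 1)
random_fcn <- function(n, p_edge = 0.5) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  d <- runif(nrow(pairs), 0.2, 1)
  structure(list(
    m = n,
    edges = data.frame(i = pairs[, 1], j = pairs[, 2], d = d, w = 1 / d),
    pt_level = NA_real_, source_kind = "pseudo",
    labels = embedfcn::roi_labels(n)
  ), class = "fcn")
}

# small planted-cohort spec shared by recovery-flavoured tests
# (scaled-down ROI count keeps the suite fast; planted nodes sit at the
# same indices as the full-size default)
small_planted_spec <- function(n_per_group, seed, n_rois = 36) {
  embedfcn::synthetic_spec(n_per_group, n_per_group, n_rois = n_rois,
                           n_timepoints = 100,
                           planted_nodes = embedfcn::strong_planted_nodes(n_rois),
                           master_seed = seed)
}
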