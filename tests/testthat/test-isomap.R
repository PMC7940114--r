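# geometric fixtures with known intrinsic dimension (scaled into [0, 1]
# so they are valid pseudo-distances)
line_fixture <- function(n = 5) {
  pts <- matrix(seq_len(n) / n, ncol = 1)
  dist_matrix(as.matrix(dist(pts)), "pseudo")
}

plane_in_10d <- function(n = 30, seed = 77) {
  withr::with_seed(seed, {
    uv <- matrix(runif(n * 2), n, 2) / 2
    basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
    pts <- uv %*% t(basis)
  })
  list(pts = pts, D = dist_matrix(as.matrix(dist(pts)), "pseudo"))
}

test_that("knn graph links k nearest neighbours with union symmetrization", {
  # three collinear points: middle point is everyone's nearest neighbour
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3) / 10
  g <- knn_graph(dist_matrix(d, "pseudo"), k = 1)
  expect_identical(g$edges[, c("i", "j")],
                   data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  expect_true(g$connected)
  expect_equal(g$edges$w, 1 / g$edges$d)

  # complete graph at k = M - 1
  withr::with_seed(5, {
    p <- matrix(rnorm(24), 8, 3)
  })
  D <- dist_matrix(as.matrix(dist(p)) / 10, "pseudo")
  gc <- knn_graph(D, k = 7)
  expect_identical(nrow(gc$edges), 28L)
})

test_that("fragmented graphs raise an error naming components", {
  # two well-separated 5-point clusters
  withr::with_seed(6, {
    a <- matrix(rnorm(10, sd = 0.1), 5, 2)
    b <- matrix(rnorm(10, mean = 50, sd = 0.1), 5, 2)
  })
  D <- dist_matrix(as.matrix(dist(rbind(a, b))) / 100, "pseudo")
  expect_error(knn_graph(D, k = 2), "2 components",
               class = "embedfcn_fragmentation_error")
  expect_warning(g <- knn_graph(D, k = 2, on_fragmented = "largest"),
                 "largest component")
  expect_identical(g$m, 5L)
})

test_that("geodesic distances match Floyd-Warshall on random graphs", {
  # chain a-b-c: geodesic a..c is the two-hop sum
  d <- matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3, 3)
  g <- knn_graph(dist_matrix(d / 10, "pseudo"), k = 1)
  dg <- geodesic_matrix(g)
  expect_equal(dg$entries[1, 3], 0.2)
  expect_identical(dg$kind, "geodesic")

  withr::with_seed(14, {
    for (rep in 1:50) {
      pts <- matrix(rnorm(10 * 3), 10, 3)
      D <- dist_matrix(as.matrix(dist(pts)) / 20, "pseudo")
      g <- knn_graph(D, k = sample(3:5, 1))
      len <- matrix(Inf, g$m, g$m)
      len[cbind(g$edges$i, g$edges$j)] <- g$edges$d
      len[cbind(g$edges$j, g$edges$i)] <- g$edges$d
      expect_equal(geodesic_matrix(g)$entries,
                   unname(oracle_floyd_warshall(len)),
                   ignore_attr = TRUE, tolerance = 1e-9)
    }
  })
})

test_that("geodesics never exceed direct edges and obey triangle inequality", {
  withr::with_seed(15, {
    pts <- matrix(rnorm(12 * 4), 12, 4)
  })
  D <- dist_matrix(as.matrix(dist(pts)) / 20, "pseudo")
  g <- knn_graph(D, k = 4)
  dg <- geodesic_matrix(g)$entries
  for (r in seq_len(nrow(g$edges)))
    expect_lte(dg[g$edges$i[r], g$edges$j[r]], g$edges$d[r] + 1e-12)
  m <- nrow(dg)
  for (i in 1:m) for (j in 1:m) for (k in 1:m)
    expect_lte(dg[i, j], dg[i, k] + dg[k, j] + 1e-9)
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  # 5 points on a line: 1-D embedding reproduces all distances
  res <- classical_mds(line_fixture(5), p_max = 4)
  expect_identical(res$p_used, 1L)
  expect_lt(max(abs(res$eigenvalues[-1])), 1e-9)
  dy <- as.matrix(dist(res$coordinates[, 1, drop = FALSE]))
  expect_equal(dy, unname(line_fixture(5)$entries), ignore_attr = TRUE,
               tolerance = 1e-9)

  # 6 random points in 3-space, p = 3 recovers the distance matrix
  withr::with_seed(8, {
    pts <- matrix(rnorm(18), 6, 3)
  })
  D <- as.matrix(dist(pts))
  res3 <- classical_mds(dist_matrix(D, "geodesic"), p_max = 5)
  dy3 <- as.matrix(dist(res3$coordinates[, 1:3]))
  expect_equal(dy3, unname(D), ignore_attr = TRUE, tolerance = 1e-9)

  expect_true(all(diff(res3$eigenvalues) <= 1e-9))
})

test_that("classical MDS agrees with the base-R implementation", {
  withr::with_seed(9, {
    pts <- matrix(rnorm(40), 10, 4)
  })
  D <- as.matrix(dist(pts))
  res <- classical_mds(dist_matrix(D, "geodesic"), p_max = 4)
  ref <- cmdscale(D, k = 4, eig = TRUE)
  expect_equal(res$eigenvalues[1:4], ref$eig[1:4], tolerance = 1e-8)
  # coordinates agree up to per-axis sign
  for (j in 1:4)
    expect_equal(unname(abs(res$coordinates[, j])),
                 unname(abs(ref$points[, j])), tolerance = 1e-6)
})

test_that("residual variance is zero for exact embeddings and errors on degenerate input", {
  fx <- plane_in_10d()
  res <- classical_mds(fx$D, p_max = 5)
  expect_equal(residual_variance(fx$D, res$coordinates[, 1:2]), 0,
               tolerance = 1e-10)
  expect_error(residual_variance(fx$D, matrix(0, 30, 2)),
               class = "embedfcn_degenerate_error")
  rv1 <- residual_variance(fx$D, res$coordinates[, 1, drop = FALSE])
  expect_gt(rv1, residual_variance(fx$D, res$coordinates[, 1:2]))
})

test_that("plane-in-10D fixture is recognised as two-dimensional", {
  # complete neighbour graph: the Euclidean input is metric, so geodesics
  # equal the direct distances and the embedding is exact at p = 2
  fx <- plane_in_10d()
  res <- isomap_embed(fx$D, k = 29, p_max = 10)
  expect_lt(res$residual_variances[2], 1e-6)
  expect_true(all(diff(res$residual_variances) <= 1e-9))
  prof <- eigengap_profile(list(res), n_top = 10)
  expect_gt(sum(prof$eigengap[1:2]), 0.99 * sum(abs(prof$eigengap)))
})

test_that("eigengap profile averages pairwise differences across subjects", {
  mk <- function(ev) structure(list(eigenvalues = ev, p_used = 1L,
                                    residual_variances = 0.5),
                               class = "embedding_result")
  single <- eigengap_profile(list(mk(c(4, 2, 1, 1))), n_top = 4)
  expect_equal(single$eigengap, c(2, 1, 0))
  two <- eigengap_profile(list(mk(c(4, 2, 1, 1)), mk(c(6, 2, 2, 0))), n_top = 4)
  expect_equal(two$eigengap, c(3, 0.5, 1))
  # short eigenvalue vectors are zero-padded
  padded <- eigengap_profile(list(mk(c(3, 1))), n_top = 4)
  expect_equal(padded$eigengap, c(2, 1, 0))
  expect_error(eigengap_profile(list()), class = "embedfcn_validation_error")
})

test_that("embedded distance matrices are consistent with the coordinates", {
  fx <- plane_in_10d()
  res <- classical_mds(fx$D, p_max = 5)
  E2 <- embedded_distance_matrix(res, 2)
  expect_identical(E2$kind, "embedded")
  expect_equal(E2$entries, t(E2$entries))
  expect_true(all(diag(E2$entries) == 0))
  # full rank on an exact fixture recovers the input distances
  expect_equal(E2$entries, unname(fx$D$entries), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(embedded_distance_matrix(res, res$p_used + 1),
               class = "embedfcn_validation_error")
})

test_that("embedding objective beats random same-shape configurations", {
  # sum of squared (geodesic - embedded) discrepancies at the MDS solution
  # is below that of random coordinate matrices
  fx <- plane_in_10d(n = 20, seed = 123)
  g <- knn_graph(fx$D, k = 5)
  dg <- geodesic_matrix(g)
  res <- classical_mds(dg, p_max = 2)
  objective <- function(coords) {
    dy <- as.matrix(dist(coords))
    sum((dg$entries - dy)^2)
  }
  obj_mds <- objective(res$coordinates[, 1:2])
  withr::with_seed(99, {
    rand_obj <- replicate(50, objective(matrix(rnorm(40), 20, 2)))
  })
  expect_true(all(obj_mds <= rand_obj))
})
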