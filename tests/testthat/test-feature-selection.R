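# planted two-class design: features `signal` shifted between groups
planted_design <- function(n, p, signal, shift, seed) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    for (k in seq_along(signal))
      X[y == 1L, signal[k]] <- X[y == 1L, signal[k]] + shift[k]
  })
  list(X = X, y = y)
}

test_that("lasso path is all-zero at lambda_max and solves OLS at tiny lambda", {
  d <- planted_design(40, 10, signal = 3, shift = 2, seed = 1)
  Xs <- scale(d$X)
  lmax <- max(abs(crossprod(Xs, d$y - mean(d$y)))) / nrow(Xs)
  fit <- lasso_path(d$X, d$y, lambdas = c(lmax * 1.01, lmax * 1e-6))
  expect_true(all(fit$coefficients[, 1] == 0))
  # near-zero penalty approaches the least-squares solution
  ols <- coef(lm(d$y ~ Xs))[-1]
  expect_equal(unname(fit$coefficients[, 2]), unname(ols), tolerance = 1e-4)
})

test_that("lasso on orthonormal designs equals the soft-threshold closed form", {
  withr::with_seed(2, {
    n <- 64
    # orthonormal mean-zero columns scaled to unit sample SD
    c0 <- scale(matrix(rnorm(n * 8), n, 8), center = TRUE, scale = FALSE)
    q <- qr.Q(qr(c0))
    X <- q * sqrt(n - 1)
    y <- as.integer(runif(n) > 0.5)
  })
  colnames(X) <- paste0("f", 1:8)
  sdv <- apply(X, 2, sd)
  Xs <- sweep(X, 2, sdv, "/")
  bls <- crossprod(Xs, y - mean(y)) / colSums(Xs^2)   # per-column LS coefficient
  gram <- crossprod(Xs) / n
  for (lam in c(0.01, 0.05, 0.1)) {
    fit <- lasso_path(X, y, lambdas = lam)
    # soft threshold of the least-squares coefficients, on the 1/n scale
    expected <- sign(bls) * pmax(abs(bls) - lam / diag(gram), 0)
    expect_equal(unname(fit$coefficients[, 1]), unname(drop(expected)),
                 tolerance = 1e-6)
  }
})

test_that("lasso support grows along the decreasing lambda path", {
  d <- planted_design(50, 30, signal = c(2, 9, 17), shift = c(2, -2, 1.5),
                      seed = 3)
  fit <- lasso_path(d$X, d$y)
  sizes <- unname(colSums(fit$coefficients != 0))
  expect_identical(sizes[1], 0)
  expect_gte(sizes[length(sizes)], 3)
  # monotone up to occasional single-feature drop-outs along the path
  expect_true(all(diff(sizes) >= -1))
  expect_error(lasso_path(d$X, c(d$y[-1], 2L)),
               class = "embedfcn_validation_error")
})

test_that("coordinate-descent path agrees with an independent reference solver", {
  skip_if_not_installed("glmnet")
  withr::with_seed(41, {
    n <- 50; p <- 25
    X <- matrix(rnorm(n * p), n, p) %*%
      (matrix(rnorm(p * p, sd = 0.2), p, p) + diag(p))
    colnames(X) <- paste0("f", 1:p)
    y <- as.integer(runif(n) > 0.5)
  })
  fit <- lasso_path(X, y)
  Xs <- scale(X)
  ref <- glmnet::glmnet(Xs, y, family = "gaussian",
                        lambda = fit$lambda_path, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  # coefficients agree where the problem is well conditioned ...
  upper <- 1:75
  # the two solvers use different convergence criteria; agreement to
  # 1e-3 on standardized coefficients is well past selection relevance
  expect_lt(max(abs(fit$coefficients[, upper] -
                      as.matrix(ref$beta)[, upper])), 1e-3)
  # ... and the attained objective matches everywhere (deep-path
  # coefficients may drift along flat directions of correlated designs)
  obj <- function(b, a0, lam)
    sum((y - a0 - Xs %*% b)^2) / (2 * n) + lam * sum(abs(b))
  for (i in c(85, 95, 100)) {
    o_mine <- obj(fit$coefficients[, i], fit$intercepts[i], fit$lambda_path[i])
    o_ref <- obj(as.matrix(ref$beta)[, i], ref$a0[i], fit$lambda_path[i])
    expect_lt(abs(o_mine - o_ref), 1e-4)
  }
})

test_that("one-SD LOOCV selection recovers a dominant planted feature", {
  hits <- 0L
  for (r in 1:20) {
    d <- planted_design(40, 15, signal = 3, shift = 4, seed = 100 + r)
    sel <- lasso_select_loocv(d$X, d$y)
    if (3L %in% sel$selected) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("one-SD LOOCV selection stays near-null on permuted labels", {
  # with labels independent of X the rule must not build real models:
  # selections collapse to at most a couple of spurious features.
  # (A fully empty set is rare by construction: under leave-one-out the
  # intercept-only model always tips the training mean away from the
  # held-out subject, so the null end of the path never looks good.)
  sizes <- integer(20)
  for (r in 1:20) {
    withr::with_seed(300 + r, {
      X <- matrix(rnorm(40 * 15), 40, 15,
                  dimnames = list(NULL, paste0("f", 1:15)))
      y <- sample(rep(0:1, each = 20))
    })
    sizes[r] <- length(lasso_select_loocv(X, y)$selected)
  }
  expect_lte(stats::median(sizes), 2)
  expect_lte(max(sizes), 5)
})

test_that("duplicating every subject preserves the path and the planted pick", {
  d <- planted_design(30, 12, signal = 5, shift = 3, seed = 7)
  # the penalized objective is invariant to duplicating the sample, so
  # the coefficient path is reproduced lambda for lambda (up to the
  # n-1 sample-SD factor entering the standardization)
  f1 <- lasso_path(d$X, d$y)
  f2 <- lasso_path(rbind(d$X, d$X), c(d$y, d$y), lambdas = f1$lambda_path)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 0.05)
  # the cross-validated folds change (each subject's twin stays in
  # training), but the dominant planted feature is selected either way
  sel1 <- lasso_select_loocv(d$X, d$y)
  sel2 <- lasso_select_loocv(rbind(d$X, d$X), c(d$y, d$y))
  expect_true(5L %in% sel1$selected)
  expect_true(5L %in% sel2$selected)
})

test_that("rf MDG ranks a perfectly separating feature first", {
  withr::with_seed(5, {
    n <- 60
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * 100), n, 100,
                dimnames = list(NULL, paste0("f", 1:100)))
    X[, 40] <- y + rnorm(n, sd = 0.05)   # near-perfect separator
  })
  for (r in 1:10) {
    rk <- rf_gini_ranking(X, y, runs = 3, trees = 150, seed = 50 + r)
    expect_identical(rk$retained[1], 40L)
    expect_true(all(rk$mdg >= 0))
  }
  expect_length(rf_gini_ranking(X, y, runs = 1, trees = 50, seed = 1)$retained,
                5L)  # ceil(0.05 * 100)
})

test_that("retained list length is the 5% ceiling", {
  withr::with_seed(6, {
    X <- matrix(rnorm(30 * 420), 30, 420,
                dimnames = list(NULL, paste0("f", 1:420)))
    y <- rep(0:1, each = 15)
  })
  rk <- rf_gini_ranking(X, y, runs = 1, trees = 30, seed = 2)
  expect_length(rk$retained, 21L)
})

test_that("one-tree mean decrease in Gini matches a hand computation", {
  # a single deterministic tree (all samples in bag, all features tried):
  # route the training data through the fitted tree and accumulate
  # p(t) * [G(t) - pL G(tL) - pR G(tR)] per splitting feature
  withr::with_seed(9, {
    n <- 10
    y <- rep(0:1, each = 5)
    X <- cbind(a = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) + rnorm(n, sd = 0.01),
               b = rnorm(n))
  })
  rf <- withr::with_seed(1, randomForest::randomForest(
    x = X, y = factor(y), ntree = 1, mtry = 2, nodesize = 1,
    replace = FALSE, sampsize = n))
  tree <- randomForest::getTree(rf, 1, labelVar = FALSE)
  gini <- function(lab) {
    p <- table(factor(lab, levels = 0:1)) / length(lab)
    1 - sum(p^2)
  }
  mdg_hand <- c(a = 0, b = 0)
  walk <- function(node, idx) {
    if (tree[node, "status"] == -1L || length(idx) == 0) return(invisible())
    v <- tree[node, "split var"]
    s <- tree[node, "split point"]
    left <- idx[X[idx, v] <= s]
    right <- idx[X[idx, v] > s]
    dec <- gini(y[idx]) -
      length(left) / length(idx) * gini(y[left]) -
      length(right) / length(idx) * gini(y[right])
    nm <- colnames(X)[v]
    mdg_hand[nm] <<- mdg_hand[nm] + length(idx) / n * dec
    walk(tree[node, "left daughter"], left)
    walk(tree[node, "right daughter"], right)
  }
  walk(1L, seq_len(n))
  imp <- randomForest::importance(rf, type = 2)[, 1] / n
  expect_equal(unname(imp[c("a", "b")]), unname(mdg_hand), tolerance = 1e-9)
})

test_that("subset search steps by two and breaks ties toward simplicity", {
  withr::with_seed(12, {
    n <- 40
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * 60), n, 60,
                dimnames = list(NULL, paste0("f", 1:60)))
    X[, 10] <- X[, 10] + 3 * y
    X[, 25] <- X[, 25] - 3 * y
  })
  rk <- rf_gini_ranking(X, y, runs = 3, trees = 150, seed = 4)
  sel <- rf_subset_select(X, y, rk)
  expect_identical(sel$subset_cv$size, seq(1L, length(rk$retained), by = 2L))
  expect_identical(sel$chosen_size, sel$subset_cv$size[
    which.max(sel$subset_cv$accuracy)])
  # which.max takes the first maximum, so exact ties prefer fewer features
  expect_true(all(sel$subset_cv$accuracy[sel$subset_cv$size == sel$chosen_size]
                  >= sel$subset_cv$accuracy))
})

test_that("rf pipeline recovers a planted two-feature design", {
  hits <- 0L
  for (r in 1:10) {
    withr::with_seed(700 + r, {
      n <- 40
      y <- rep(0:1, each = n / 2)
      X <- matrix(rnorm(n * 50), n, 50,
                  dimnames = list(NULL, paste0("f", 1:50)))
      X[, 7] <- X[, 7] + 2.5 * y
      X[, 31] <- X[, 31] - 2.5 * y
    })
    rk <- rf_gini_ranking(X, y, runs = 5, trees = 200, seed = r)
    sel <- rf_subset_select(X, y, rk)
    if (all(c(7L, 31L) %in% sel$selected)) hits <- hits + 1L
  }
  expect_gte(hits / 10, 0.8)
})

test_that("selectors are pure functions of data and seed", {
  d <- planted_design(24, 20, signal = c(4, 11), shift = c(2.5, -2.5), seed = 15)
  expect_identical(lasso_select_loocv(d$X, d$y)$selected,
                   lasso_select_loocv(d$X, d$y)$selected)
  r1 <- rf_gini_ranking(d$X, d$y, runs = 2, trees = 100, seed = 9)
  r2 <- rf_gini_ranking(d$X, d$y, runs = 2, trees = 100, seed = 9)
  expect_identical(r1$mdg, r2$mdg)
})
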