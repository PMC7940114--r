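# ---- shared helpers ---------------------------------------------------------

# standardize columns using training statistics; constant columns dropped
# (with a warning) or frozen to zero
standardize_train <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
  keep <- sdv > pmax(abs(mu), 1) * 1e-10   # constants up to rounding noise
  if (!all(keep))
    warning(sprintf("dropping %d constant feature column(s)", sum(!keep)),
            call. = FALSE)
  xs <- sweep(x[, keep, drop = FALSE], 2L, mu[keep])
  xs <- sweep(xs, 2L, sdv[keep], "/")
  list(x = xs, mu = mu, sd = sdv, keep = keep)
}

apply_standardization <- function(x, st) {
  xs <- sweep(x[, st$keep, drop = FALSE], 2L, st$mu[st$keep])
  sweep(xs, 2L, st$sd[st$keep], "/")
}

check_binary_labels <- function(y) {
  if (!all(y %in% c(0L, 1L)))
    abort_embedfcn("labels must be 0/1", "embedfcn_validation_error")
  as.integer(y)
}

# ---- LASSO ------------------------------------------------------------------

#' Squared-error LASSO path
#'
#' Solves `argmin_a (1/2n) ||y - a0 - X a||^2 + lambda ||a||_1` along a
#' decreasing lambda path by cyclical coordinate descent with warm
#' starts and active-set sweeps (compiled; soft-threshold updates on
#' standardized columns).  Features are standardized to zero mean /
#' unit SD from the provided subjects; the intercept is unpenalized.
#' At `lambda >= max_j |<x_j, y - ybar>| / n` every coefficient is
#' zero.
#'
#' @param X Subjects x features numeric matrix (named columns).
#' @param y Binary 0/1 labels.
#' @param lambdas Optional decreasing lambda sequence; by default 100
#'   log-spaced values from `lambda_max` down to `0.001 * lambda_max`.
#' @param nlambda,lambda_min_ratio Path shape when `lambdas` is `NULL`.
#' @param thresh Coordinate-descent convergence tolerance (default
#'   `1e-9`; the cross-validated selector uses `1e-5`, ample for 0/1
#'   misclassification decisions).
#' @return Object of class `lasso_fit`: `lambda_path`, `coefficients`
#'   (features x lambdas, on the standardized scale, zero rows for
#'   dropped constants), `intercepts`, `standardization`.
#' @export
lasso_path <- function(X, y, lambdas = NULL, nlambda = 100L,
                       lambda_min_ratio = 0.001, thresh = 1e-9) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  st <- standardize_train(X)
  n <- nrow(X)
  if (is.null(lambdas)) {
    lmax <- max(abs(crossprod(st$x, y - mean(y)))) / n
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  }
  lambdas <- sort(as.numeric(lambdas), decreasing = TRUE)
  fit <- lasso_cd_path(st$x, as.numeric(y), lambdas, thresh, 150L)
  full <- matrix(0, ncol(X), length(lambdas),
                 dimnames = list(colnames(X), NULL))
  full[st$keep, ] <- fit$beta
  structure(list(lambda_path = lambdas,
                 coefficients = full,
                 intercepts = as.numeric(fit$a0),
                 standardization = st),
            class = "lasso_fit")
}

#' LASSO feature selection with LOOCV and the one-standard-deviation rule
#'
#' Leave-one-out cross-validation over subjects on a shared lambda path
#' (computed from all provided subjects).  Within each fold features are
#' re-standardized from the training subjects only, the path is refit,
#' and the held-out subject is classified as 1 when its fitted linear
#' response exceeds 0.5.  Per lambda the misclassification rate and the
#' spread of the 0/1 fold errors are recorded; the chosen lambda is the
#' largest (most parsimonious) whose CV error is within one spread unit
#' of the best model's error.  The model is then refit on all provided
#' subjects at that lambda and the nonzero support returned.
#'
#' @inheritParams lasso_path
#' @param rule `"sd"` (default): spread = plain standard deviation of the
#'   fold errors at the minimizing lambda; `"se"`: standard error
#'   (SD / sqrt(n folds)).
#' @return Object of class `lasso_selection`: `selected` (integer feature
#'   indices), `selected_names`, `lambda_chosen`, `lambda_path`,
#'   `cv_error`, `cv_sd` (per lambda), `fit` (full-data [lasso_path()]).
#' @export
lasso_select_loocv <- function(X, y, nlambda = 100L, lambda_min_ratio = 0.001,
                               rule = c("sd", "se"), thresh = 1e-5) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  n <- nrow(X)
  if (n < 10L)
    abort_embedfcn("need at least 10 subjects for LOOCV selection",
                   "embedfcn_validation_error")
  if (length(unique(y)) < 2L)
    abort_embedfcn("both classes must be present", "embedfcn_validation_error")
  base <- suppressWarnings(lasso_path(X, y, nlambda = nlambda,
                                      lambda_min_ratio = lambda_min_ratio,
                                      thresh = thresh))
  lam <- base$lambda_path
  errs <- matrix(NA_real_, n, length(lam))
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      abort_embedfcn("a LOOCV training fold contains a single class",
                     "embedfcn_validation_error")
    st <- suppressWarnings(standardize_train(X[-i, , drop = FALSE]))
    fit <- lasso_cd_path(st$x, as.numeric(ytr), lam, thresh, 150L)
    xs <- apply_standardization(X[i, , drop = FALSE], st)
    eta <- drop(xs %*% fit$beta) + fit$a0
    errs[i, ] <- as.integer(eta > 0.5) != y[i]
  }
  cv_error <- colMeans(errs)
  cv_sd <- apply(errs, 2L, stats::sd)
  if (rule == "se") cv_sd <- cv_sd / sqrt(n)
  i_min <- which.min(cv_error)
  cutoff <- cv_error[i_min] + cv_sd[i_min]
  lambda_chosen <- max(lam[cv_error <= cutoff])
  j <- which(lam == lambda_chosen)[1L]
  selected <- which(base$coefficients[, j] != 0)
  structure(list(selected = as.integer(unname(selected)),
                 selected_names = names(selected),
                 lambda_chosen = lambda_chosen,
                 lambda_path = lam,
                 cv_error = cv_error, cv_sd = cv_sd,
                 fit = base),
            class = "lasso_selection")
}

# ---- Random forest ----------------------------------------------------------

#' Random-forest mean-decrease-Gini feature ranking
#'
#' Trains `runs` independent forests (bootstrap sampling, Gini splitting,
#' `floor(sqrt(p))` candidate features per split, trees grown to purity)
#' and averages the per-feature mean decrease in Gini impurity across
#' runs for a stable ranking.  The top 5% of features (ceiling) by
#' averaged MDG are retained, in descending order.  MDG is reported per
#' training sample, i.e. each split's impurity decrease is weighted by
#' the fraction of (in-bag) samples reaching the node, summed over the
#' feature's splits and averaged over trees.
#'
#' @inheritParams lasso_path
#' @param runs Independent forest runs, default 30.
#' @param trees Trees per forest, default 500.
#' @param seed Integer seed; run `r` uses `seed + r`.
#' @param retain_fraction Fraction of features retained, default 0.05.
#' @return Object of class `rf_ranking`: `mdg` (named, averaged),
#'   `retained` (feature indices, descending MDG), `retained_names`,
#'   `run_count`.
#' @export
rf_gini_ranking <- function(X, y, runs = 30L, trees = 500L, seed = 1L,
                            retain_fraction = 0.05) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  if (length(unique(y)) < 2L)
    abort_embedfcn("both classes must be present", "embedfcn_validation_error")
  p <- ncol(X)
  n <- nrow(X)
  yf <- factor(y, levels = c(0L, 1L))
  acc <- numeric(p)
  for (r in seq_len(runs)) {
    imp <- withr::with_seed(as.integer(seed) + r, {
      rf <- randomForest::randomForest(
        x = X, y = yf, ntree = as.integer(trees),
        mtry = max(1L, floor(sqrt(p))), nodesize = 1L)
      randomForest::importance(rf, type = 2L)[, 1L]
    })
    acc <- acc + imp / n     # per-sample scale of the weighted Gini decrease
  }
  mdg <- stats::setNames(acc / runs, colnames(X))
  n_keep <- ceiling(retain_fraction * p)
  retained <- order(mdg, decreasing = TRUE)[seq_len(n_keep)]
  structure(list(mdg = mdg, retained = as.integer(retained),
                 retained_names = colnames(X)[retained],
                 run_count = as.integer(runs)),
            class = "rf_ranking")
}

#' Subset search over a random-forest ranking
#'
#' For nested subsets of the retained ranked features of sizes 1, 3, 5,
#' ... (step 2) up to the full retained list, estimates the LOOCV
#' accuracy of the linear SVM (`C = 1`) on that subset and returns the
#' subset with the highest accuracy; ties go to the smallest subset.
#'
#' @inheritParams lasso_path
#' @param ranking An [rf_gini_ranking()] result.
#' @param C SVM regularization, default 1.
#' @return Object of class `rf_selection`: `selected` (feature indices),
#'   `selected_names`, `subset_cv` (data frame size / accuracy),
#'   `chosen_size`.
#' @export
rf_subset_select <- function(X, y, ranking, C = 1) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  if (!inherits(ranking, "rf_ranking") || length(ranking$retained) == 0L)
    abort_embedfcn("ranking must be a nonempty rf_ranking",
                   "embedfcn_validation_error")
  sizes <- seq.int(1L, length(ranking$retained), by = 2L)
  accs <- vapply(sizes, function(sz) {
    cols <- ranking$retained[seq_len(sz)]
    svm_loocv_accuracy(X[, cols, drop = FALSE], y, C = C)
  }, numeric(1L))
  best <- sizes[which.max(accs)]   # which.max takes the first (smallest) tie
  structure(list(
    selected = ranking$retained[seq_len(best)],
    selected_names = ranking$retained_names[seq_len(best)],
    subset_cv = data.frame(size = sizes, accuracy = accs),
    chosen_size = best
  ), class = "rf_selection")
}
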