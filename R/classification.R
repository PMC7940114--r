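#' Train a linear support vector machine
#'
#' Soft-margin linear SVM (hinge loss, penalty `C * sum z_i`) on
#' fold-standardized features.  Wraps the libsvm solver (via e1071) and
#' extracts the explicit primal weights `w` and bias `b`; the orientation
#' is calibrated so the decision rule is `1` when
#' `w . x_standardized + b > 0`, `0` otherwise (a response of exactly 0
#' maps to class 0).
#'
#' @param X Subjects x features numeric matrix.
#' @param y Binary 0/1 labels (both classes required).
#' @param C Regularization parameter, default 1.
#' @param standardize Standardize features from the training subjects
#'   (default `TRUE`); constant columns are frozen at zero.
#' @return Object of class `svm_model`: `w`, `b`, `C`, `mu`, `sd`
#'   (training standardization; `sd` of a constant column is set to 1).
#' @export
train_linear_svm <- function(X, y, C = 1, standardize = TRUE) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  if (length(unique(y)) < 2L)
    abort_embedfcn("both classes must be present to train an SVM",
                   "embedfcn_validation_error")
  if (ncol(X) < 1L)
    abort_embedfcn("need at least one feature", "embedfcn_validation_error")
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0] <- 1
  } else {
    mu <- rep(0, ncol(X)); sdv <- rep(1, ncol(X))
  }
  xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(x = xs, y = yf, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision function towards the first training label;
  # calibrate so positive response means class 1
  pred_svm <- as.integer(as.character(predict(fit, xs)))
  pred_wb <- as.integer(drop(xs %*% w) + b > 0)
  if (mean(pred_svm == pred_wb) < 0.5) {
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, C = C, mu = mu, sd = sdv),
            class = "svm_model")
}

#' Predict classes with a linear SVM model
#'
#' @param object An `svm_model`.
#' @param newdata Subjects x features matrix on the original scale.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2L, object$mu), 2L, object$sd, "/")
  as.integer(drop(xs %*% object$w) + object$b > 0)
}

# LOOCV accuracy of the linear SVM on a fixed feature set (used by the
# random-forest subset search)
svm_loocv_accuracy <- function(X, y, C = 1) {
  n <- nrow(X)
  correct <- vapply(seq_len(n), function(i) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) return(NA)
    m <- train_linear_svm(X[-i, , drop = FALSE], ytr, C = C)
    predict(m, X[i, , drop = FALSE]) == y[i]
  }, logical(1L))
  mean(correct, na.rm = TRUE)
}

#' Confusion-matrix statistics
#'
#' Patients (label 1) are positives, controls (label 0) negatives.
#' Accuracy = (TP + TN) / n, sensitivity (true-positive rate) =
#' TP / (TP + FN), specificity (true-negative rate) = TN / (TN + FP),
#' all as percentages.
#'
#' @param predictions,truths Equal-length 0/1 vectors.
#' @return List with `confusion` (named TP/FP/TN/FN counts), `accuracy`,
#'   `sensitivity`, `specificity` (percent).
#' @export
confusion_stats <- function(predictions, truths) {
  if (length(predictions) == 0L || length(predictions) != length(truths))
    abort_embedfcn("predictions and truths must be nonempty and equal length",
                   "embedfcn_validation_error")
  predictions <- check_binary_labels(predictions)
  truths <- check_binary_labels(truths)
  tp <- sum(predictions == 1L & truths == 1L)
  fp <- sum(predictions == 1L & truths == 0L)
  tn <- sum(predictions == 0L & truths == 0L)
  fn <- sum(predictions == 0L & truths == 1L)
  list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    accuracy = 100 * (tp + tn) / length(truths),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  )
}

# run the inner feature-selection procedure for one outer fold
run_selector <- function(X, y, selector, seed, selector_args) {
  if (selector == "lasso") {
    args <- c(list(X = X, y = y), selector_args)
    sel <- do.call(lasso_select_loocv, args)
    list(selected = sel$selected, names = sel$selected_names, detail = sel)
  } else {
    rank_args <- c(list(X = X, y = y, seed = seed),
                   selector_args[names(selector_args) %in%
                                   c("runs", "trees", "retain_fraction")])
    ranking <- do.call(rf_gini_ranking, rank_args)
    sel <- rf_subset_select(X, y, ranking)
    list(selected = sel$selected, names = sel$selected_names, detail = sel)
  }
}

# fallback when a fold selects nothing: single top-ranked feature
# (largest |score| of a univariate correlation with the labels)
fallback_feature <- function(X, y) {
  sc <- abs(suppressWarnings(stats::cor(X, y)))
  sc[is.na(sc)] <- -Inf
  which.max(sc)
}

#' Double leave-one-out cross-validation with inner feature selection
#'
#' The outer loop holds out one subject at a time; the inner procedure
#' (LASSO with its own LOOCV and one-SD rule, or random-forest MDG
#' ranking plus subset search) runs on the remaining `n - 1` subjects
#' only, a linear SVM (`C = 1`) is trained on those subjects restricted
#' to the selected features, and the held-out subject is predicted.
#' The held-out subject never influences standardization, selection, or
#' training, so the aggregated confusion matrix is an unbiased estimate
#' of generalization.  Each feature can be selected at most `n` times.
#'
#' Seeds fan out per fold (`seed + fold index`) so any single fold is
#' independently reproducible.  If a fold's selector returns an empty
#' set, the single feature most correlated with the training labels is
#' used instead (with a message).
#'
#' @param X Subjects x features numeric matrix with column names.
#' @param y Binary 0/1 labels.
#' @param selector `"lasso"` or `"rf"`.
#' @param seed Integer master seed.
#' @param C SVM regularization, default 1.
#' @param selector_args Named list of extra arguments for the selector
#'   (e.g. `runs`, `trees` for `"rf"`; `nlambda`, `rule` for
#'   `"lasso"`).
#' @return Object of class `cv_outcome`: `n_subjects`, `folds` (data
#'   frame: `held_out`, `true`, `predicted`, `n_selected`, `selected`
#'   as a semicolon-joined string), `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `selection_counts` (named integer
#'   vector over features ever selected, descending).
#' @export
double_loocv <- function(X, y, selector = c("lasso", "rf"), seed = 1L,
                         C = 1, selector_args = list()) {
  selector <- match.arg(selector)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- check_binary_labels(y)
  n <- nrow(X)
  if (n < 10L)
    abort_embedfcn("need at least 10 subjects", "embedfcn_validation_error")
  if (length(unique(y)) < 2L)
    abort_embedfcn("both classes must be present", "embedfcn_validation_error")
  counts <- integer(ncol(X))
  folds <- vector("list", n)
  preds <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    sel <- run_selector(Xtr, ytr, selector, as.integer(seed) + i, selector_args)
    chosen <- sel$selected
    if (length(chosen) == 0L) {
      chosen <- fallback_feature(Xtr, ytr)
      message(sprintf("fold %d: empty selection; falling back to top feature '%s'",
                      i, colnames(X)[chosen]))
    }
    counts[chosen] <- counts[chosen] + 1L
    model <- train_linear_svm(Xtr[, chosen, drop = FALSE], ytr, C = C)
    preds[i] <- predict(model, X[i, chosen, drop = FALSE])
    folds[[i]] <- data.frame(
      held_out = rownames(X)[i] %||% as.character(i),
      true = y[i], predicted = preds[i],
      n_selected = length(chosen),
      selected = paste(colnames(X)[chosen], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  stats <- confusion_stats(preds, y)
  names(counts) <- colnames(X)
  counts <- sort(counts[counts > 0L], decreasing = TRUE)
  structure(c(list(n_subjects = n, folds = do.call(rbind, folds),
                   selection_counts = counts, selector = selector,
                   seed = as.integer(seed)),
              stats),
            class = "cv_outcome")
}

#' @export
print.cv_outcome <- function(x, ...) {
  cat(sprintf("<cv_outcome> %d subjects, selector = %s\n", x$n_subjects, x$selector))
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  top <- utils::head(x$selection_counts, 5L)
  cat("  top selections:",
      paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Per-feature group comparison (Welch's t-test, Bonferroni)
#'
#' Welch's unequal-variance t-test of every feature between the two
#' groups; a feature is flagged significant when its raw p-value is
#' below `alpha / n_features` (Bonferroni over all features tested,
#' e.g. 0.05/420 for the 84-ROI feature vector).  Features with zero
#' variance in both groups are flagged not-testable (`NA`).
#'
#' @param feature_table Subjects x features numeric matrix.
#' @param labels Binary 0/1 group labels (both groups >= 2 subjects).
#' @param alpha Family-wise error rate, default 0.05.
#' @return Data frame: `feature`, `statistic`, `p_value`, `significant`.
#' @export
group_compare <- function(feature_table, labels, alpha = 0.05) {
  X <- as.matrix(feature_table)
  labels <- check_binary_labels(labels)
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L)
    abort_embedfcn("both groups need at least 2 subjects",
                   "embedfcn_validation_error")
  nf <- ncol(X)
  res <- lapply(seq_len(nf), function(j) {
    a <- X[labels == 0L, j]; b <- X[labels == 1L, j]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(c(NA_real_, NA_real_))
    tt <- stats::t.test(b, a, var.equal = FALSE)
    c(unname(tt$statistic), tt$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(
    feature = colnames(X) %||% paste0("f", seq_len(nf)),
    statistic = res[, 1L],
    p_value = res[, 2L],
    significant = res[, 2L] < alpha / nf,
    stringsAsFactors = FALSE
  )
}
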