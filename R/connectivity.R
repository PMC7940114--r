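#' Distance matrix container
#'
#' Light S3 wrapper around a symmetric non-negative matrix with zero
#' diagonal.  `kind` records the provenance of the distances:
#' `"pseudo"` (cross-correlation pseudo-distance, entries in `[0, 1]`),
#' `"geodesic"` (shortest-path lengths on a neighbour graph) or
#' `"embedded"` (Euclidean distances among embedded coordinates).
#'
#' @param entries Numeric M x M matrix.
#' @param kind One of `"pseudo"`, `"geodesic"`, `"embedded"`.
#' @return Object of class `fcn_dist` with fields `entries`, `m`, `kind`.
#' @export
dist_matrix <- function(entries, kind = c("pseudo", "geodesic", "embedded")) {
  kind <- match.arg(kind)
  entries <- as.matrix(entries)
  m <- nrow(entries)
  if (ncol(entries) != m)
    abort_embedfcn("distance matrix must be square", "embedfcn_validation_error")
  if (max(abs(entries - t(entries))) > 1e-8)
    abort_embedfcn("distance matrix must be symmetric", "embedfcn_validation_error")
  entries <- (entries + t(entries)) / 2
  diag(entries) <- 0
  if (any(entries < -1e-12))
    abort_embedfcn("distance matrix must be nonnegative", "embedfcn_validation_error")
  entries[entries < 0] <- 0
  if (kind == "pseudo" && any(entries > 1 + 1e-9))
    abort_embedfcn("pseudo-distances must lie in [0, 1]", "embedfcn_validation_error")
  if (is.null(rownames(entries))) {
    rownames(entries) <- colnames(entries) <- roi_labels(m)
  }
  structure(list(entries = entries, m = m, kind = kind), class = "fcn_dist")
}

#' @export
print.fcn_dist <- function(x, ...) {
  cat(sprintf("<fcn_dist> %d x %d, kind = %s\n", x$m, x$m, x$kind))
  invisible(x)
}

# pull a plain matrix out of fcn_dist or pass a matrix through
dist_entries <- function(D) {
  if (inherits(D, "fcn_dist")) D$entries else as.matrix(D)
}

#' Lagged cross-correlation between two series
#'
#' Sample cross-correlation at a signed lag `l`, using the non-circular
#' (truncated-overlap) estimator: cross-products are summed over the
#' `N - |l|` aligned pairs, while means and standard deviations are those
#' of the full series (the convention of classical time-series
#' cross-correlation; it keeps the value in `[-1, 1]`).  At `l = 0` this is
#' the plain Pearson correlation.  Positive `l` shifts `x` forward: the
#' value correlates `x[t + l]` with `y[t]`.
#'
#' @param x,y Numeric series of equal length.
#' @param l Integer lag, `|l| < length(x)`.
#' @return Correlation value in `[-1, 1]`.
#' @export
cross_correlation <- function(x, y, l) {
  n <- length(x)
  if (length(y) != n)
    abort_embedfcn("series must have equal length", "embedfcn_validation_error")
  l <- as.integer(l)
  if (abs(l) >= n)
    abort_embedfcn("|lag| must be smaller than the series length",
                   "embedfcn_validation_error")
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0)
    abort_embedfcn("zero-variance series in cross-correlation",
                   "embedfcn_degenerate_error")
  xc <- x - mean(x); yc <- y - mean(y)
  if (l >= 0) {
    s <- sum(xc[(1 + l):n] * yc[1:(n - l)])
  } else {
    s <- sum(xc[1:(n + l)] * yc[(1 - l):n])
  }
  s / (n * sx * sy)
}

#' Cross-correlation profile over a window of lags
#'
#' Evaluates [cross_correlation()] at every lag in `-l_max .. l_max`; with
#' the default `l_max = 3` each ROI pair yields 7 correlation scores (three
#' backward shifts, the zero-lag Pearson correlation, three forward
#' shifts).
#'
#' @param x,y Numeric series of equal length.
#' @param l_max Maximum lag (>= 0).
#' @return Named numeric vector of length `2 * l_max + 1` (names are the
#'   lags), class `ccf_profile`.
#' @export
ccf_profile <- function(x, y, l_max = 3L) {
  l_max <- as.integer(l_max)
  if (l_max < 0)
    abort_embedfcn("l_max must be >= 0", "embedfcn_validation_error")
  lags <- seq.int(-l_max, l_max)
  v <- vapply(lags, function(l) cross_correlation(x, y, l), numeric(1L))
  structure(stats::setNames(v, lags), l_max = l_max, class = "ccf_profile")
}

#' Cross-correlation pseudo-distance matrix of a subject
#'
#' For every ROI pair the pseudo-distance is one minus the maximum absolute
#' cross-correlation over lags `-l_max .. l_max`:
#' `d(i, j) = 1 - max_l |CCF(i, j, l)|`.  Strongly correlated regions --
#' even at a small phase shift -- are thus close.  The result is symmetric
#' with zero diagonal and entries in `[0, 1]`.
#'
#' @param ts A [roi_ts()] subject (or plain T x M matrix).
#' @param l_max Maximum lag searched, default 3.
#' @return A [dist_matrix()] of kind `"pseudo"`.
#' @export
pseudo_distance_matrix <- function(ts, l_max = 3L) {
  x <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  n <- nrow(x); m <- ncol(x)
  l_max <- as.integer(l_max)
  if (l_max < 0 || l_max >= n)
    abort_embedfcn("l_max must be in [0, nrow - 1)", "embedfcn_validation_error")
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  if (any(sds == 0)) {
    bad <- colnames(x)[which(sds == 0)[1L]] %||% which(sds == 0)[1L]
    abort_embedfcn(sprintf("ROI '%s' is constant; pseudo-distance undefined", bad),
                   "embedfcn_degenerate_error")
  }
  xc <- sweep(x, 2L, colMeans(x))
  denom <- n * tcrossprod(sds)
  best <- abs(crossprod(xc)) / denom              # lag 0
  for (l in seq_len(l_max)) {
    cl <- crossprod(xc[(1 + l):n, , drop = FALSE], xc[1:(n - l), , drop = FALSE]) / denom
    best <- pmax(best, abs(cl), abs(t(cl)))       # +l and -l
  }
  d <- 1 - best
  dimnames(d) <- list(colnames(x), colnames(x))
  dist_matrix(d, "pseudo")
}
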