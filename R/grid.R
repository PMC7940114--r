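#' Parameter-sweep configuration
#'
#' Defaults reproduce the full analysis sweep: proportional thresholds
#' 20--50% in steps of 5 (7 levels), ISOMAP neighbourhoods `k = 6..20`
#' (15 values) and embedding dimensions `p = 2..5` (4 values), for both
#' FCN constructions and each selector -- 7 x 15 x 4 ISOMAP
#' configurations plus 7 correlation configurations = 427 rows per
#' selector.
#'
#' @param methods Subset of `c("correlation", "isomap")`.
#' @param pt_levels Proportional threshold percentages.
#' @param k_values ISOMAP neighbour counts.
#' @param p_values Embedding dimensions.
#' @param selectors Subset of `c("lasso", "rf")`.
#' @param master_seed Integer seed for the whole sweep.
#' @return Object of class `grid_config`.
#' @export
grid_config <- function(methods = c("correlation", "isomap"),
                        pt_levels = seq(20, 50, by = 5),
                        k_values = 6:20,
                        p_values = 2:5,
                        selectors = c("lasso", "rf"),
                        master_seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  selectors <- match.arg(selectors, several.ok = TRUE)
  structure(list(methods = methods, pt_levels = pt_levels,
                 k_values = as.integer(k_values),
                 p_values = as.integer(p_values),
                 selectors = selectors,
                 master_seed = as.integer(master_seed)),
            class = "grid_config")
}

#' Enumerate the configurations of a sweep
#'
#' @param cfg A [grid_config()].
#' @return Data frame with one row per configuration: `method`, `p`,
#'   `k` (`NA` for correlation), `pt`, `selector`.
#' @export
enumerate_grid <- function(cfg) {
  rows <- list()
  for (sel in cfg$selectors) {
    if ("correlation" %in% cfg$methods)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "correlation", p = NA_integer_, k = NA_integer_,
        pt = cfg$pt_levels, selector = sel, stringsAsFactors = FALSE)
    if ("isomap" %in% cfg$methods)
      rows[[length(rows) + 1L]] <- expand.grid(
        method = "isomap", p = cfg$p_values, k = cfg$k_values,
        pt = cfg$pt_levels, selector = sel,
        stringsAsFactors = FALSE)[, c("method", "p", "k", "pt", "selector")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full parameter sweep on a cohort
#'
#' Executes the complete pipeline (distances, optional embedding,
#' thresholding, node measures, [double_loocv()]) for every
#' configuration of the grid, appending accuracy, sensitivity,
#' specificity and the top selected features per row.  Per-subject
#' pseudo-distances and per-`k` embeddings are computed once and
#' reused, so each grid row equals the result of running that
#' configuration alone.  Configurations whose k-NN graph fragments for
#' some subject are skipped with a recorded reason.  Cohort-level
#' eigengap / residual-variance diagnostics are attached for the
#' largest `k` that worked.
#'
#' @param cohort List of [roi_ts()] subjects.
#' @param cfg A [grid_config()].
#' @param l_max Maximum cross-correlation lag, default 3.
#' @param selector_args Named list of extra selector arguments (see
#'   [double_loocv()]).
#' @param top_n How many top selected features to report per row,
#'   default 3.
#' @return List: `results` (data frame; `best` flags the best row per
#'   method x selector), `skipped` (data frame of skipped
#'   configurations), `diagnostics` (from [eigengap_profile()], or
#'   `NULL`).
#' @export
run_grid <- function(cohort, cfg, l_max = 3L, selector_args = list(),
                     top_n = 3L) {
  grid <- enumerate_grid(cfg)
  y <- vapply(cohort, function(s) s$label, integer(1L))
  dists <- lapply(cohort, pseudo_distance_matrix, l_max = l_max)
  p_need <- if (length(cfg$p_values)) max(cfg$p_values) else 2L

  emb_cache <- list()   # per-k list of embedding results (or an error marker)
  get_embeddings <- function(k) {
    key <- as.character(k)
    if (is.null(emb_cache[[key]])) {
      emb_cache[[key]] <<- tryCatch(
        lapply(dists, isomap_embed, k = k, p_max = max(15L, p_need)),
        embedfcn_fragmentation_error = function(e) conditionMessage(e))
    }
    emb_cache[[key]]
  }

  results <- list()
  skipped <- list()
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    feats <- if (g$method == "correlation") {
      lapply(seq_along(cohort), function(s) {
        f <- proportional_threshold(dists[[s]], g$pt)
        feature_vector(f, seed = cfg$master_seed + s)
      })
    } else {
      emb <- get_embeddings(g$k)
      if (is.character(emb)) {
        skipped[[length(skipped) + 1L]] <-
          cbind(g, reason = emb, stringsAsFactors = FALSE)
        next
      }
      lapply(seq_along(cohort), function(s) {
        D <- embedded_distance_matrix(emb[[s]], g$p)
        f <- proportional_threshold(D, g$pt)
        feature_vector(f, seed = cfg$master_seed + s)
      })
    }
    X <- do.call(rbind, feats)
    rownames(X) <- vapply(cohort, function(s) s$subject_id, character(1L))
    cv <- double_loocv(X, y, selector = g$selector, seed = cfg$master_seed,
                       selector_args = selector_args)
    top <- utils::head(cv$selection_counts, top_n)
    results[[length(results) + 1L]] <- cbind(
      g,
      data.frame(accuracy = cv$accuracy, sensitivity = cv$sensitivity,
                 specificity = cv$specificity,
                 top_features = paste(sprintf("%s(%d)", names(top), top),
                                      collapse = ";"),
                 stringsAsFactors = FALSE))
  }
  results <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(results)) {
    results$best <- FALSE
    for (mm in unique(results$method)) for (ss in unique(results$selector)) {
      idx <- which(results$method == mm & results$selector == ss)
      if (length(idx))
        results$best[idx[which.max(results$accuracy[idx])]] <- TRUE
    }
    rownames(results) <- NULL
  }
  diagnostics <- NULL
  ok_k <- names(emb_cache)[vapply(emb_cache, is.list, logical(1L))]
  if (length(ok_k)) {
    kk <- max(as.integer(ok_k))
    diagnostics <- eigengap_profile(emb_cache[[as.character(kk)]])
    diagnostics$k <- kk
  }
  list(results = results,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       diagnostics = diagnostics)
}
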