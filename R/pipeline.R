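#' Build the cohort feature table
#'
#' Runs the per-subject pipeline up to the node-measure feature vector:
#' pseudo-distance matrix, optional ISOMAP embedding (`method =
#' "isomap"`), proportional threshold, five local measures.  Louvain
#' seeds are derived from the master seed and the subject index so the
#' table is a pure function of `(cohort, parameters, seed)`.
#'
#' @param cohort List of [roi_ts()] subjects.
#' @param pt Proportional threshold percentage.
#' @param method `"correlation"` (threshold the pseudo-distances
#'   directly) or `"isomap"` (threshold the embedded Euclidean
#'   distances).
#' @param k Neighbours for the ISOMAP graph (required for
#'   `method = "isomap"`).
#' @param p Embedding dimension (required for `method = "isomap"`).
#' @param l_max Maximum cross-correlation lag, default 3.
#' @param seed Master seed, default 1.
#' @param p_max Dimensions retained in the embedding diagnostics,
#'   default 15.
#' @param restarts Louvain restarts per subject, default 10.
#' @return List: `X` (subjects x `5 * M` named feature matrix), `y`
#'   (labels), `subject_ids`, `embeddings` (list of `embedding_result`,
#'   `NULL` for `"correlation"`).
#' @export
build_feature_table <- function(cohort, pt, method = c("correlation", "isomap"),
                                k = NULL, p = NULL, l_max = 3L, seed = 1L,
                                p_max = 15L, restarts = 10L) {
  method <- match.arg(method)
  if (method == "isomap" && (is.null(k) || is.null(p)))
    abort_embedfcn("method = 'isomap' requires k and p", "embedfcn_validation_error")
  embeddings <- if (method == "isomap") vector("list", length(cohort)) else NULL
  rows <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    subj <- cohort[[s]]
    D <- pseudo_distance_matrix(subj, l_max = l_max)
    if (method == "isomap") {
      res <- isomap_embed(D, k = k, p_max = max(p_max, p))
      embeddings[[s]] <- res
      D <- embedded_distance_matrix(res, p)
    }
    f <- proportional_threshold(D, pt)
    rows[[s]] <- feature_vector(f, seed = as.integer(seed) + s,
                                restarts = restarts)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort, function(s) s$subject_id, character(1L))
  list(X = X,
       y = vapply(cohort, function(s) s$label, integer(1L)),
       subject_ids = rownames(X),
       embeddings = embeddings)
}
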