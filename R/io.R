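#' Read a cohort from a manifest file
#'
#' The manifest is a CSV with columns `subject_id`, `label` (0 control /
#' 1 patient) and `path`; each path points to a delimited text file of
#' `T` rows x `M` columns with a header row of ROI labels shared across
#' subjects (relative paths are resolved against the manifest's
#' directory).  Column order is harmonized to the first subject's
#' header; a permuted header is reordered with a message, a mismatched
#' set of labels is an error.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return List of [roi_ts()] subjects.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    abort_embedfcn(sprintf("manifest not found: %s", manifest_path),
                   "embedfcn_io_error")
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "label", "path")
  if (!all(req %in% names(man)))
    abort_embedfcn("manifest must have columns subject_id, label, path",
                   "embedfcn_validation_error")
  if (anyDuplicated(man$subject_id))
    abort_embedfcn("duplicated subject_id in manifest", "embedfcn_validation_error")
  if (!all(man$label %in% c(0L, 1L)))
    abort_embedfcn("manifest labels must be 0 or 1", "embedfcn_validation_error")
  base <- dirname(manifest_path)
  header <- NULL
  lapply(seq_len(nrow(man)), function(r) {
    path <- man$path[r]
    if (!is_abs_path(path)) path <- file.path(base, path)
    if (!file.exists(path))
      abort_embedfcn(sprintf("subject '%s': file not found: %s",
                             man$subject_id[r], path), "embedfcn_io_error")
    x <- utils::read.delim(path, check.names = FALSE)
    x <- as.matrix(x)
    if (!is.numeric(x))
      abort_embedfcn(sprintf("subject '%s': non-numeric cell in %s",
                             man$subject_id[r], path), "embedfcn_validation_error")
    if (is.null(header)) {
      header <<- colnames(x)
    } else {
      if (!setequal(colnames(x), header))
        abort_embedfcn(sprintf("subject '%s': ROI header does not match the cohort",
                               man$subject_id[r]), "embedfcn_validation_error")
      if (!identical(colnames(x), header)) {
        message(sprintf("subject '%s': reordering ROI columns to match the cohort",
                        man$subject_id[r]))
        x <- x[, header, drop = FALSE]
      }
    }
    roi_ts(man$subject_id[r], man$label[r], x)
  })
}

is_abs_path <- function(p) grepl("^(/|[A-Za-z]:)", p)

# full-precision numeric formatting for round-trippable text files
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a distance matrix or coordinate matrix as TSV
#'
#' Distance matrices are written with ROI row and column labels;
#' coordinate matrices (`embedding_result` coordinates or any M x p
#' matrix) with ROI rows and dimension columns.  Values are written at
#' full precision so a read-back reproduces them exactly.
#'
#' @param x A [dist_matrix()], or a numeric matrix.
#' @param path Output file path.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "fcn_dist")) x$entries else as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- roi_labels(nrow(m))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("dim", seq_len(ncol(m)))
  out <- apply(m, c(1L, 2L), fmt_full)
  df <- data.frame(label = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a matrix written by [write_matrix()]
#'
#' @param path File path.
#' @param kind If not `NULL`, wrap the result as a [dist_matrix()] of
#'   this kind.
#' @return Numeric matrix (or [dist_matrix()]).
#' @export
read_matrix <- function(path, kind = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- apply(as.matrix(df[, -1L, drop = FALSE]), c(1L, 2L), as.numeric)
  rownames(m) <- df[[1L]]
  if (is.null(kind)) m else dist_matrix(m, kind)
}

#' Write a synthetic cohort to disk
#'
#' One tab-delimited time-series file per subject (T rows x M columns,
#' ROI-label header), a manifest CSV (`subject_id`, `label`, `path`)
#' and, when the spec has planted nodes, a ground-truth JSON.
#'
#' @param cohort List of [roi_ts()] subjects (e.g. from
#'   [generate_cohort()]).
#' @param dir Output directory (created if missing).
#' @param spec Optional [synthetic_spec()]; when given,
#'   `truth.json` records [planted_truth()].
#' @return Path of the manifest file.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort, function(s) {
    p <- paste0(s$subject_id, ".tsv")
    out <- apply(s$data, c(1L, 2L), fmt_full)
    utils::write.table(out, file.path(dir, p), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1L))
  man <- data.frame(
    subject_id = vapply(cohort, function(s) s$subject_id, character(1L)),
    label = vapply(cohort, function(s) s$label, integer(1L)),
    path = paths, stringsAsFactors = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  if (!is.null(spec))
    jsonlite::write_json(planted_truth(spec), file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
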