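#' Read a beta-value matrix and its sample metadata
#'
#' Reads a TSV with a `probe_id` first column and one column per sample, plus
#' a sample metadata CSV/TSV mapping each sample to a patient id and a tissue
#' role. Values are checked to be numeric and in \[0, 1\]; offending cells are
#' reported by probe and sample.
#'
#' @param path Path to the beta TSV (probes in rows, header = sample ids).
#' @param meta_path Path to the metadata table with columns
#'   `sample`, `patient`, `role`.
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path, meta_path) {
  values <- read_matrix_tsv(path, what = "beta-value")
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("Beta-value out of [0, 1] at probe '%s', sample '%s' (%g).",
                  rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                  values[bad[1, , drop = FALSE]]))
  }
  meta <- readr::read_delim(meta_path, show_col_types = FALSE,
                            delim = guess_delim(meta_path))
  unknown <- setdiff(colnames(values), meta$sample)
  if (length(unknown)) {
    abort(paste0("Samples absent from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  beta_matrix(values, meta)
}

#' Write a beta-value matrix and sample metadata
#'
#' @param beta A [beta_matrix].
#' @param path Output TSV path for values (first column `probe_id`).
#' @param meta_path Output CSV path for sample metadata.
#' @return `beta` invisibly.
#' @export
write_beta_matrix <- function(beta, path, meta_path) {
  write_matrix_tsv(beta$values, path)
  readr::write_csv(beta$sample_meta, meta_path)
  invisible(beta)
}

#' Read or write a plain numeric probes-by-samples TSV
#'
#' Shared reader for detection-p matrices and other numeric sidecars: first
#' column `probe_id`, remaining columns numeric per sample.
#'
#' @param path File path.
#' @param what Label used in error messages.
#' @return A numeric matrix with probe rownames.
#' @export
read_matrix_tsv <- function(path, what = "value") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "probe_id") abort("First column must be `probe_id`.")
  if (anyDuplicated(df$probe_id)) {
    abort(sprintf("Duplicated probe id '%s' in %s.",
                  df$probe_id[duplicated(df$probe_id)][1], path))
  }
  mat <- as.matrix(df[-1])
  if (!is.numeric(mat)) {
    badcol <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))][1]
    abort(sprintf("Non-numeric %s cells in column '%s' of %s.",
                  what, badcol, path))
  }
  rownames(mat) <- df$probe_id
  mat
}

#' @rdname read_matrix_tsv
#' @param mat Numeric matrix with rownames.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "probe_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read probe annotation
#'
#' @param path TSV with columns `probe_id`, `chromosome`, `cgi` (logical),
#'   `gene`.
#' @return A tibble, one row per probe.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "chromosome", "cgi", "gene")
  if (!all(need %in% names(ann))) {
    abort(paste0("Annotation must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ann$probe_id)) abort("Duplicated probe ids in annotation.")
  ann$cgi <- as.logical(ann$cgi)
  ann
}

#' Read a two-platform expression export
#'
#' @param path TSV of log2 intensities, first column `feature_id`.
#' @param meta_path CSV with columns `sample`, `patient`, `role`, `platform`.
#' @param map_path Optional TSV with columns `feature_id`, `accession`.
#' @return An [expr_matrix].
#' @export
read_expr_matrix <- function(path, meta_path, map_path = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "feature_id") abort("First column must be `feature_id`.")
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$feature_id
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
  map <- if (!is.null(map_path)) {
    readr::read_tsv(map_path, show_col_types = FALSE, progress = FALSE)
  }
  expr_matrix(mat, meta, map)
}

#' @rdname read_expr_matrix
#' @param x An [expr_matrix].
#' @export
write_expr_matrix <- function(x, path, meta_path, map_path = NULL) {
  df <- tibble::as_tibble(x$values, rownames = "feature_id")
  readr::write_tsv(df, path)
  readr::write_csv(x$sample_meta, meta_path)
  if (!is.null(map_path)) readr::write_tsv(x$feature_map, map_path)
  invisible(x)
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
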