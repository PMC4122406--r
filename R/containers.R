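#' Construct a beta-value matrix object
#'
#' Bundles a probes-by-samples matrix of methylation beta-values (fractions in
#' \[0, 1\], `NA` allowed for failed detections) with per-sample metadata:
#' which patient each column belongs to and whether it is a tumor or an
#' adjacent non-tumorous tissue.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_meta Data frame with columns `sample`, `patient`, `role`
#'   (`"tumor"` or `"adjacent"`), one row per column of `values`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs probe rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("Duplicated probe ids.")
  if (anyDuplicated(colnames(values))) abort("Duplicated sample ids.")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort(sprintf("Beta-values must lie in [0, 1]; observed range [%g, %g].",
                  rng[1], rng[2]))
  }
  sample_meta <- as_tibble(sample_meta)
  need <- c("sample", "patient", "role")
  if (!all(need %in% names(sample_meta))) {
    abort("`sample_meta` must have columns sample, patient, role.")
  }
  if (!all(sample_meta$role %in% c("tumor", "adjacent"))) {
    abort("`role` must be 'tumor' or 'adjacent'.")
  }
  missing_meta <- setdiff(colnames(values), sample_meta$sample)
  if (length(missing_meta)) {
    abort(paste0("Samples missing from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  structure(list(values = values, sample_meta = sample_meta),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples (%d tumor, %d adjacent)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_meta$role == "tumor"),
              sum(x$sample_meta$role == "adjacent")))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

# Column subsets keep metadata aligned.
subset_samples <- function(beta, keep) {
  beta_matrix(beta$values[, keep, drop = FALSE],
              beta$sample_meta[beta$sample_meta$sample %in%
                                 colnames(beta$values[, keep, drop = FALSE]), ])
}

# Tumor-only value matrix, columns ordered as in the object.
tumor_values <- function(beta) {
  beta$values[, beta$sample_meta$sample[beta$sample_meta$role == "tumor"],
              drop = FALSE]
}

adjacent_values <- function(beta) {
  beta$values[, beta$sample_meta$sample[beta$sample_meta$role == "adjacent"],
              drop = FALSE]
}

#' Construct an expression matrix object
#'
#' Features-by-samples log2 intensities with a feature-to-accession map and
#' per-sample platform/batch labels, mirroring two-platform microarray
#' exports.
#'
#' @param values Numeric matrix of log2 intensities, feature rownames and
#'   sample colnames.
#' @param sample_meta Data frame with columns `sample`, `patient`, `role`,
#'   `platform`.
#' @param feature_map Data frame with columns `feature_id`, `accession`
#'   mapping array probes to gene accessions; defaults to identity.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, sample_meta, feature_map = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs feature rownames and sample colnames.")
  }
  if (any(!is.finite(values))) abort("Expression values must be finite.")
  sample_meta <- as_tibble(sample_meta)
  need <- c("sample", "patient", "role", "platform")
  if (!all(need %in% names(sample_meta))) {
    abort("`sample_meta` must have columns sample, patient, role, platform.")
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  if (anyNA(sample_meta$sample)) abort("Every sample needs metadata.")
  if (is.null(feature_map)) {
    feature_map <- tibble(feature_id = rownames(values),
                          accession = rownames(values))
  }
  feature_map <- as_tibble(feature_map)
  if (!all(rownames(values) %in% feature_map$feature_id)) {
    abort("`feature_map` must cover every feature.")
  }
  structure(list(values = values, sample_meta = sample_meta,
                 feature_map = feature_map),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, platforms: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_meta$platform), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)
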