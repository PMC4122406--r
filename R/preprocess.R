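#' Mask unreliable measurements by detection p-value
#'
#' Beta-values whose detection p-value exceeds `alpha` (strictly greater
#' than) are set missing, and probes that end up missing in more than
#' `max_missing` of samples are dropped entirely.
#'
#' @param beta A [beta_matrix].
#' @param detp Numeric matrix of detection p-values aligned to
#'   `beta$values`.
#' @param alpha Detection threshold; values with p > alpha are masked
#'   (p = alpha exactly is retained).
#' @param max_missing Per-probe missing fraction above which the probe is
#'   dropped.
#' @return A [beta_matrix] with a `removal` attribute: tibble of dropped
#'   probes and counts of masked cells.
#' @export
filter_detection <- function(beta, detp, alpha = 0.05, max_missing = 0.2) {
  if (!identical(dim(beta$values), dim(detp))) {
    abort("`detp` must have the same shape as the beta matrix.")
  }
  if (!is.null(rownames(detp)) &&
      !identical(rownames(detp), rownames(beta$values))) {
    abort("`detp` probe order differs from the beta matrix.")
  }
  values <- beta$values
  mask <- detp > alpha
  n_masked <- sum(mask, na.rm = TRUE)
  values[mask] <- NA_real_
  miss_frac <- rowMeans(is.na(values))
  drop <- miss_frac > max_missing
  out <- beta_matrix(values[!drop, , drop = FALSE], beta$sample_meta)
  attr(out, "removal") <- tibble(
    probe_id = rownames(values)[drop],
    missing_fraction = miss_frac[drop]
  )
  attr(out, "n_masked") <- n_masked
  out
}

#' Drop probes on the sex chromosomes
#'
#' Removes every probe annotated to chrX/chrY (the labels `"X"`, `"Y"`,
#' `"chrX"`, `"chrY"` are all recognized) to avoid gender-driven clustering.
#'
#' @param beta A [beta_matrix].
#' @param ann Probe annotation tibble covering every probe in `beta`.
#' @return A [beta_matrix] without sex-chromosome probes; the number removed
#'   is stored in attribute `n_sex_removed`.
#' @export
drop_sex_chromosomes <- function(beta, ann) {
  probes <- rownames(beta$values)
  missing <- setdiff(probes, ann$probe_id)
  if (length(missing)) {
    abort(paste0("Probes without annotation: ",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..."))
  }
  chr <- ann$chromosome[match(probes, ann$probe_id)]
  chr_norm <- toupper(sub("^chr", "", chr, ignore.case = TRUE))
  sex <- chr_norm %in% c("X", "Y")
  out <- beta_matrix(beta$values[!sex, , drop = FALSE], beta$sample_meta)
  attr(out, "n_sex_removed") <- sum(sex)
  out
}

#' Quantile-normalize the columns of a matrix
#'
#' Forces every column onto a common empirical distribution: the pointwise
#' mean of the column-sorted values. Ties within a column receive the mean
#' of their tied rank-quantiles; missing values are ignored when building
#' the reference and preserved as missing in the output. Columns with
#' unequal numbers of observed values are aligned to the reference by
#' linear interpolation over rank-quantiles.
#'
#' @param values Numeric matrix (probes x samples), `NA` allowed.
#' @return A matrix of the same shape with identical per-column
#'   distributions.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) abort("Need at least 2 columns.")
  n_obs <- colSums(!is.na(values))
  if (any(n_obs == 0)) {
    j <- which(n_obs == 0)[1]
    lab <- colnames(values)[j] %||% as.character(j)
    abort(sprintf("Column '%s' is entirely missing.", lab))
  }
  n_ref <- nrow(values)
  grid <- if (n_ref == 1) 0.5 else seq(0, 1, length.out = n_ref)
  # reference distribution: mean across columns of sorted values, columns
  # with missing entries interpolated onto the common rank grid
  ref_cols <- vapply(seq_len(ncol(values)), function(j) {
    v <- sort(values[, j])
    if (length(v) == n_ref) return(v)
    if (length(v) == 1) return(rep(v, n_ref))
    stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid,
                  rule = 2)$y
  }, numeric(n_ref))
  ref <- rowMeans(ref_cols)

  out <- values
  for (j in seq_len(ncol(values))) {
    obs <- !is.na(values[, j])
    m <- sum(obs)
    r <- rank(values[obs, j], ties.method = "average")
    p <- if (m == 1) 0.5 else (r - 1) / (m - 1)
    out[obs, j] <- stats::approx(grid, ref, xout = p, rule = 2)$y
  }
  out
}

#' Within-replicate concordance
#'
#' Squared Pearson correlation (coefficient of determination) for every
#' within-group pair of replicate samples, the standard array
#' reproducibility report.
#'
#' @param beta A [beta_matrix].
#' @param replicate_groups Named list; each element a character vector of
#'   >= 2 sample ids forming one replicate group.
#' @return A tibble with columns `group`, `sample_1`, `sample_2`,
#'   `r_squared`.
#' @export
replicate_concordance <- function(beta, replicate_groups) {
  purrr::imap_dfr(replicate_groups, function(ids, grp) {
    if (length(ids) < 2) {
      abort(sprintf("Replicate group '%s' has fewer than 2 samples.", grp))
    }
    pairs <- utils::combn(ids, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]
      b <- pairs[2, i]
      r <- stats::cor(beta$values[, a], beta$values[, b],
                      use = "pairwise.complete.obs")
      tibble(group = grp, sample_1 = a, sample_2 = b, r_squared = r^2)
    })
  })
}

#' Run the full methylation preprocessing chain
#'
#' Detection filtering, sex-chromosome removal, then joint quantile
#' normalization of tumors and adjacent tissues together.
#'
#' @inheritParams filter_detection
#' @inheritParams drop_sex_chromosomes
#' @param normalize Quantile-normalize after filtering (default TRUE).
#' @return A filtered, normalized [beta_matrix].
#' @export
preprocess_beta <- function(beta, detp, ann, alpha = 0.05,
                            max_missing = 0.2, normalize = TRUE) {
  out <- filter_detection(beta, detp, alpha = alpha,
                          max_missing = max_missing)
  out <- drop_sex_chromosomes(out, ann)
  if (normalize) {
    vals <- quantile_normalize(out$values)
    vals <- pmin(pmax(vals, 0), 1)
    out2 <- beta_matrix(vals, out$sample_meta)
    attr(out2, "removal") <- attr(out, "removal")
    attr(out2, "n_sex_removed") <- attr(out, "n_sex_removed")
    out <- out2
  }
  out
}
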