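#' Differential methylation between tumor and adjacent tissue
#'
#' Per-probe two-group comparison of tumor versus adjacent beta-values with
#' Benjamini-Hochberg control. A probe is called significant when its
#' adjusted p-value is below `q_max` and the absolute mean beta-difference
#' strictly exceeds `min_delta`; significant probes are classified as
#' hypermethylated (delta > 0) or hypomethylated.
#'
#' @param beta A [beta_matrix] containing both tissue roles.
#' @param q_max FDR threshold (strict `<`).
#' @param min_delta Minimum absolute mean beta-difference (strict `>`).
#' @param method `"anova"` (ordinary one-way ANOVA on the tissue factor) or
#'   `"moderated"` (empirical-Bayes moderated t).
#' @param paired Use within-patient paired differences (default unpaired).
#' @return A `diffmeth_result` tibble: `probe_id`, `delta_beta`,
#'   `statistic`, `p`, `q`, `significant`, `direction`
#'   (`hyper`/`hypo`/`none`), with the thresholds stored as attributes.
#' @export
differential_methylation <- function(beta, q_max = 0.05, min_delta = 0.1,
                                     method = c("anova", "moderated"),
                                     paired = FALSE) {
  method <- match.arg(method)
  roles <- beta$sample_meta$role
  if (!all(c("tumor", "adjacent") %in% roles)) {
    abort("Both tumor and adjacent samples are required.")
  }
  groups <- factor(roles, levels = c("adjacent", "tumor"))
  res <- if (method == "anova") {
    two_group_anova(beta$values, groups, paired = paired,
                    pair_id = beta$sample_meta$patient)
  } else {
    moderated_t(beta$values, groups)
  }
  out <- res |>
    dplyr::transmute(
      probe_id = .data$feature,
      delta_beta = .data$effect,
      statistic = .data$statistic,
      p = .data$p, q = .data$q,
      significant = .data$q < q_max & abs(.data$delta_beta) > min_delta,
      direction = dplyr::case_when(
        .data$significant & .data$delta_beta > 0 ~ "hyper",
        .data$significant ~ "hypo",
        .default = "none"
      )
    )
  attr(out, "q_max") <- q_max
  attr(out, "min_delta") <- min_delta
  class(out) <- c("diffmeth_result", class(out))
  out
}

#' Summarize a differential-methylation call set
#'
#' @param x A `diffmeth_result`.
#' @param ... Unused.
#' @return A one-row tibble: probes tested, significant, hyper and hypo
#'   counts and the hypo fraction.
#' @export
glance.diffmeth_result <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_significant = sum(x$significant),
    n_hyper = sum(x$direction == "hyper"),
    n_hypo = sum(x$direction == "hypo"),
    frac_hypo = ifelse(sum(x$significant) > 0,
                       sum(x$direction == "hypo") / sum(x$significant), NA_real_)
  )
}

#' CpG-island localization of differential probes
#'
#' For the hyper- and hypomethylated sets separately: the proportion of
#' probes inside CpG islands, and a Fisher's exact test of the set's CGI
#' membership against the rest of the array (2x2: in-set/not x CGI/not).
#'
#' @param diff A `diffmeth_result`.
#' @param ann Probe annotation covering every tested probe.
#' @return A tibble with columns `direction`, `n`, `n_cgi`, `prop_cgi`,
#'   `background_prop_cgi`, `odds_ratio`, `p`.
#' @export
cgi_enrichment <- function(diff, ann) {
  missing <- setdiff(diff$probe_id, ann$probe_id)
  if (length(missing)) abort("Annotation does not cover all probes.")
  cgi <- ann$cgi[match(diff$probe_id, ann$probe_id)]
  purrr::map_dfr(c("hyper", "hypo"), function(dir) {
    in_set <- diff$direction == dir
    n <- sum(in_set)
    if (n == 0) {
      warn(sprintf("No %smethylated probes; enrichment p is NA.", dir))
      return(tibble(direction = dir, n = 0L, n_cgi = 0L, prop_cgi = NA_real_,
                    background_prop_cgi = mean(cgi[!in_set]),
                    odds_ratio = NA_real_, p = NA_real_))
    }
    tab <- table(in_set = factor(in_set, c(TRUE, FALSE)),
                 cgi = factor(cgi, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    tibble(direction = dir, n = n, n_cgi = sum(cgi[in_set]),
           prop_cgi = mean(cgi[in_set]),
           background_prop_cgi = mean(cgi[!in_set]),
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
}

#' Volcano-plot coordinates
#'
#' @param diff A `diffmeth_result`.
#' @return A tibble with `probe_id`, `delta_beta`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano_table <- function(diff) {
  tibble(probe_id = diff$probe_id, delta_beta = diff$delta_beta,
         neg_log10_p = -log10(diff$p), significant = diff$significant)
}

#' Two-way correlation-distance dendrogram orders
#'
#' Average-linkage agglomerative clustering with distance `1 - r` (Pearson)
#' over probes and over samples, the standard two-way heat-map layout.
#' Constant vectors, whose correlation is undefined, are assigned distance
#' 1 to everything (maximally dissimilar).
#'
#' @param beta A [beta_matrix].
#' @param probe_subset Probe ids to cluster (non-empty).
#' @return A list with `probe_order`, `sample_order` (leaf orders),
#'   `probe_heights`, `sample_heights` (merge heights), and the two
#'   `hclust` objects.
#' @export
cluster_heatmap_order <- function(beta, probe_subset) {
  if (length(probe_subset) == 0) abort("`probe_subset` is empty.")
  missing <- setdiff(probe_subset, rownames(beta$values))
  if (length(missing)) abort("Unknown probes in `probe_subset`.")
  x <- beta$values[probe_subset, , drop = FALSE]
  hp <- stats::hclust(cor_dist(t(x)), method = "average")
  hs <- stats::hclust(cor_dist(x), method = "average")
  list(probe_order = rownames(x)[hp$order],
       sample_order = colnames(x)[hs$order],
       probe_heights = hp$height, sample_heights = hs$height,
       probe_hclust = hp, sample_hclust = hs)
}

# 1 - Pearson distance between the COLUMNS of x; undefined correlations
# (constant columns) are treated as maximally distant.
cor_dist <- function(x) {
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}
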