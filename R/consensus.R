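#' Select the most variable probes among tumors
#'
#' Probes ranked by standard deviation across tumor samples; the top
#' `ceiling(fraction * n)` are returned, ties broken by probe id.
#'
#' @param beta_tumors Probes-by-tumors matrix (or a [beta_matrix], from
#'   which tumor columns are taken).
#' @param fraction Fraction of probes to keep, in (0, 1].
#' @return Character vector of selected probe ids.
#' @export
select_variable_probes <- function(beta_tumors, fraction = 0.05) {
  if (inherits(beta_tumors, "beta_matrix")) {
    beta_tumors <- tumor_values(beta_tumors)
  }
  if (nrow(beta_tumors) == 0) abort("Empty matrix.")
  check_fraction(fraction, "fraction", allow_zero = FALSE)
  sds <- apply(beta_tumors, 1, stats::sd, na.rm = TRUE)
  n_keep <- ceiling(fraction * nrow(beta_tumors))
  ord <- order(-sds, rownames(beta_tumors))
  rownames(beta_tumors)[ord[seq_len(n_keep)]]
}

#' Cluster samples once
#'
#' The base clusterer used inside consensus resampling. Hierarchical mode is
#' average linkage on `1 - Pearson` between samples, cut into `k` groups;
#' k-means mode runs Lloyd's algorithm on standardized features with
#' k-means++ style seeding, keeping the best of `restarts` starts by
#' within-cluster sum of squares.
#'
#' @param data Samples-by-features numeric matrix.
#' @param k Number of clusters (>= 2, <= number of samples).
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param restarts Restarts for k-means.
#' @return Integer cluster labels, one per sample (row).
#' @export
base_cluster <- function(data, k, method = c("hierarchical", "kmeans"),
                         restarts = 10L) {
  method <- match.arg(method)
  n <- nrow(data)
  if (k < 2) abort("`k` must be >= 2.")
  if (k > n) abort("`k` cannot exceed the number of samples.")
  if (method == "hierarchical") {
    hc <- stats::hclust(cor_dist(t(data)), method = "average")
    stats::cutree(hc, k = k)
  } else {
    x <- scale(data)
    x[, !is.finite(colSums(x))] <- 0  # constant features carry no signal
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = centers, algorithm = "Lloyd",
                      iter.max = 100)
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    unname(best$cluster)
  }
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE] + matrix(stats::rnorm(k * ncol(x), 0, 1e-8), k)
}

#' Consensus matrix by subsampled clustering
#'
#' Repeatedly draws a fraction of the samples without replacement, clusters
#' the subsample, and records for every pair of samples the fraction of
#' co-sampled iterations in which they landed in the same cluster (the
#' consensus index).
#'
#' @param data Samples-by-features matrix (rownames = sample ids).
#' @param k Number of clusters passed to the base clusterer.
#' @param n_iter Number of resampling iterations.
#' @param subsample Fraction of samples drawn each iteration, in (0, 1\];
#'   `ceiling(subsample * n)` samples are used.
#' @param method Base clustering method, see [base_cluster()].
#' @param seed Seed for the resampling stream.
#' @return A `consensus_matrix` object: list with `consensus` (samples x
#'   samples, diagonal 1), `together` and `cosampled` count matrices, and
#'   the run parameters.
#' @export
consensus_matrix <- function(data, k, n_iter = 1000L, subsample = 0.8,
                             method = c("hierarchical", "kmeans"),
                             seed = 1L) {
  method <- match.arg(method)
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  check_fraction(subsample, "subsample", allow_zero = FALSE)
  n <- nrow(data)
  m <- ceiling(subsample * n)
  if (m < k) abort("Subsample size is smaller than `k`.")
  ids <- rownames(data) %||% as.character(seq_len(n))

  together <- matrix(0, n, n, dimnames = list(ids, ids))
  cosampled <- matrix(0, n, n, dimnames = list(ids, ids))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      labels <- base_cluster(data[idx, , drop = FALSE], k = k,
                             method = method)
      same <- outer(labels, labels, "==") * 1
      together[idx, idx] <- together[idx, idx] + same
      cosampled[idx, idx] <- cosampled[idx, idx] + 1
    }
  })
  consensus <- together / cosampled
  never <- cosampled == 0
  if (any(never[upper.tri(never)])) {
    warn("Some sample pairs were never co-sampled; their consensus is set to 0.")
    consensus[never] <- 0
  }
  diag(consensus) <- 1
  structure(list(consensus = consensus, together = together,
                 cosampled = cosampled, k = k, n_iter = n_iter,
                 subsample = subsample, method = method, seed = seed),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("<consensus_matrix> %d samples, k = %d, %d iterations (%s, %.0f%% subsampling)\n",
              nrow(x$consensus), x$k, x$n_iter, x$method, 100 * x$subsample))
  invisible(x)
}

#' Final grouping from a consensus matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - consensus`, cut into `k` groups.
#'
#' @param cm A `consensus_matrix` (or a plain consensus matrix).
#' @param k Number of groups.
#' @return Named integer labels per sample.
#' @export
cut_consensus <- function(cm, k = NULL) {
  C <- if (inherits(cm, "consensus_matrix")) cm$consensus else as.matrix(cm)
  if (is.null(k)) k <- cm$k
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  stats::cutree(hc, k = k)
}

#' Choose the number of subgroups from consensus CDFs
#'
#' Computes, for each candidate `k`, the empirical CDF of the off-diagonal
#' consensus indices, its area, the relative change in area from `k - 1`
#' (delta-area criterion; for `k = 2` the area itself), and the proportion
#' of ambiguous clustering (PAC: mass between `pac_lower` and `pac_upper`).
#' The default choice maximizes the delta-area; `criterion = "pac"`
#' minimizes PAC (ties to the smallest k).
#'
#' @param cms Named list of `consensus_matrix` objects for k = 2..k_max.
#' @param criterion `"delta_area"` or `"pac"`.
#' @param pac_lower,pac_upper PAC window bounds.
#' @return A list with `k` (the choice), `trace` (tibble of k, area,
#'   delta_area, pac) and `weak_structure` (TRUE when the chosen k still
#'   leaves more than 30% of sample pairs with ambiguous consensus, i.e.
#'   the matrix is far from binary).
#' @export
choose_k <- function(cms, criterion = c("delta_area", "pac"),
                     pac_lower = 0.1, pac_upper = 0.9) {
  criterion <- match.arg(criterion)
  if (length(cms) < 2) abort("Need >= 2 candidate k.")
  ks <- vapply(cms, function(cm) cm$k, numeric(1))
  cms <- cms[order(ks)]
  ks <- sort(ks)
  stats_tbl <- purrr::map2_dfr(cms, ks, function(cm, k) {
    v <- cm$consensus[upper.tri(cm$consensus)]
    tibble(k = k, area = cdf_area(v),
           pac = mean(v > pac_lower & v < pac_upper))
  })
  stats_tbl$delta_area <- c(stats_tbl$area[1],
                            diff(stats_tbl$area) /
                              utils::head(stats_tbl$area, -1))
  stats_tbl$delta_area <- pmax(stats_tbl$delta_area, 0)
  k_hat <- if (criterion == "delta_area") {
    stats_tbl$k[which.max(stats_tbl$delta_area)]
  } else {
    stats_tbl$k[which.min(stats_tbl$pac)]
  }
  list(k = as.integer(k_hat), trace = stats_tbl,
       weak_structure = stats_tbl$pac[stats_tbl$k == k_hat] > 0.3)
}

# Area under the empirical CDF of consensus values over [0, 1].
cdf_area <- function(v) {
  f <- stats::ecdf(v)
  x <- seq(0, 1, length.out = 201)
  sum(f(utils::head(x, -1)) * diff(x))
}

#' Iterative subgroup-discriminating feature selection
#'
#' Alternates moderated-F feature selection with consensus reclustering:
#' each round keeps the probes whose moderated F across the current
#' subgroups passes `fdr`, rebuilds the consensus matrix on the kept
#' probes, and recuts the labels. Rounds are accepted while the clustering
#' stability (mean within-cluster consensus index) does not decrease;
#' iteration stops when the feature set is unchanged between rounds or
#' `max_rounds` is reached.
#'
#' @param beta_tumors Probes-by-tumors matrix.
#' @param labels Initial subgroup labels (named by sample).
#' @param fdr FDR threshold for keeping a feature.
#' @param max_rounds Maximum selection rounds.
#' @param n_iter,subsample,method,seed Consensus parameters, see
#'   [consensus_matrix()].
#' @return A list with `features` (kept probe ids), `labels` (final
#'   labels), `converged`, `trace` (tibble: round, n_features, stability)
#'   and the final `consensus_matrix`.
#' @export
feature_select_iterate <- function(beta_tumors, labels, fdr = 0.05,
                                   max_rounds = 10L, n_iter = 1000L,
                                   subsample = 0.8,
                                   method = "hierarchical", seed = 1L) {
  k <- length(unique(labels))
  features <- rownames(beta_tumors)
  cur_labels <- labels
  cm <- NULL
  stability <- -Inf
  trace <- list()
  converged <- FALSE
  prev <- list(features = features, labels = cur_labels, cm = NULL)

  for (round in seq_len(max_rounds)) {
    counts <- table(cur_labels)
    ok_groups <- names(counts)[counts >= 2]
    if (length(ok_groups) < 2) break  # no usable contrast; keep prior state
    use <- names(cur_labels)[as.character(cur_labels) %in% ok_groups]
    mf <- moderated_f(beta_tumors[features, use, drop = FALSE],
                      cur_labels[use])
    keep <- mf$feature[mf$q < fdr]
    if (length(keep) == 0) {
      abort("Feature selection emptied the set; loosen `fdr`.")
    }
    new_cm <- consensus_matrix(t(beta_tumors[keep, , drop = FALSE]), k = k,
                               n_iter = n_iter, subsample = subsample,
                               method = method,
                               seed = derive_seed(seed, round))
    new_labels <- cut_consensus(new_cm)
    new_stab <- within_cluster_consensus(new_cm$consensus, new_labels)
    trace[[round]] <- tibble(round = round, n_features = length(keep),
                             stability = new_stab)
    if (new_stab < stability) break  # reject the round, keep previous state
    same_set <- setequal(keep, features)
    features <- keep
    cur_labels <- new_labels
    cm <- new_cm
    stability <- new_stab
    prev <- list(features = features, labels = cur_labels, cm = cm)
    if (same_set) {
      converged <- TRUE
      break
    }
  }
  list(features = prev$features, labels = prev$labels,
       converged = converged, trace = dplyr::bind_rows(trace),
       consensus = prev$cm)
}

within_cluster_consensus <- function(C, labels) {
  labels <- labels[rownames(C)]
  same <- outer(labels, labels, "==")
  ut <- upper.tri(C)
  mean(C[ut & same])
}

#' Consensus hierarchical clustering with feature selection (CHC-FS)
#'
#' The full subgroup-discovery pipeline: restrict to the most variable
#' probes among tumors, build consensus matrices over a grid of k with
#' subsampled hierarchical clustering, pick k by the delta-area criterion,
#' then iterate moderated-F feature selection against consensus
#' reclustering until the feature set stabilizes. A consensus k-means
#' variant is run on the same selected features for validation and its
#' label agreement (adjusted Rand index) reported.
#'
#' @param beta_tumors A [beta_matrix] (tumor columns are used) or a
#'   probes-by-tumors matrix.
#' @param variable_fraction Fraction of most-variable probes to start from.
#' @param k_max Largest candidate number of subgroups.
#' @param n_iter Consensus iterations per matrix.
#' @param subsample Subsampling fraction.
#' @param fdr Feature-selection FDR threshold.
#' @param max_rounds Feature-selection rounds cap.
#' @param criterion k-selection rule, see [choose_k()].
#' @param run_kmeans Also run the consensus k-means validation variant.
#' @param seed Seed; all internal streams derive from it.
#' @return A `chcfs_result`: list with `k`, `labels`, `features`,
#'   `consensus` (final consensus matrix), `k_trace` (choose_k trace),
#'   `fs_trace`, `kmeans_labels`, `kmeans_agreement`, `weak_structure`,
#'   `consensus_by_k`.
#' @export
chcfs <- function(beta_tumors, variable_fraction = 0.05, k_max = 5L,
                  n_iter = 1000L, subsample = 0.8, fdr = 0.05,
                  max_rounds = 10L, criterion = "delta_area",
                  run_kmeans = TRUE, seed = 1L) {
  if (inherits(beta_tumors, "beta_matrix")) {
    beta_tumors <- tumor_values(beta_tumors)
  }
  if (ncol(beta_tumors) < 3) abort("Need >= 3 tumors.")
  vp <- select_variable_probes(beta_tumors, variable_fraction)
  x <- t(beta_tumors[vp, , drop = FALSE])

  cms <- purrr::map(2:k_max, function(k) {
    consensus_matrix(x, k = k, n_iter = n_iter, subsample = subsample,
                     method = "hierarchical",
                     seed = derive_seed(seed, 100L + k))
  })
  sel <- choose_k(cms, criterion = criterion)
  k <- sel$k
  cm0 <- cms[[k - 1]]
  labels0 <- cut_consensus(cm0)

  fs <- feature_select_iterate(beta_tumors[vp, , drop = FALSE], labels0,
                               fdr = fdr, max_rounds = max_rounds,
                               n_iter = n_iter, subsample = subsample,
                               method = "hierarchical",
                               seed = derive_seed(seed, 200L))
  final_cm <- fs$consensus %||% cm0
  labels <- fs$labels

  km_labels <- NULL
  km_agreement <- NA_real_
  if (run_kmeans) {
    km_cm <- consensus_matrix(t(beta_tumors[fs$features, , drop = FALSE]),
                              k = k, n_iter = n_iter, subsample = subsample,
                              method = "kmeans",
                              seed = derive_seed(seed, 300L))
    km_labels <- cut_consensus(km_cm)
    km_agreement <- ari(labels, km_labels[names(labels)])
  }

  structure(list(
    k = k, labels = labels, features = fs$features, consensus = final_cm,
    k_trace = sel$trace, fs_trace = fs$trace, fs_converged = fs$converged,
    kmeans_labels = km_labels, kmeans_agreement = km_agreement,
    weak_structure = sel$weak_structure,
    consensus_by_k = cms, seed = seed
  ), class = "chcfs_result")
}

#' @export
print.chcfs_result <- function(x, ...) {
  cat(sprintf("<chcfs_result> k = %d (%s), %d features, %d tumors\n",
              x$k, if (x$weak_structure) "weak structure" else "stable",
              length(x$features), length(x$labels)))
  if (!is.na(x$kmeans_agreement)) {
    cat(sprintf("  k-means validation ARI: %.3f\n", x$kmeans_agreement))
  }
  invisible(x)
}

#' Subgroup labels as a tibble
#'
#' @param x A `chcfs_result`.
#' @param ... Unused.
#' @return A tibble with `sample`, `group`, and (when run) the k-means
#'   validation label.
#' @export
tidy.chcfs_result <- function(x, ...) {
  out <- tibble(sample = names(x$labels), group = unname(x$labels))
  if (!is.null(x$kmeans_labels)) {
    out$kmeans_group <- unname(x$kmeans_labels[out$sample])
  }
  out
}

#' One-row summary of a CHC-FS run
#'
#' @param x A `chcfs_result`.
#' @param ... Unused.
#' @return A one-row tibble: chosen k, feature count, stability, k-means
#'   agreement, weak-structure flag.
#' @export
glance.chcfs_result <- function(x, ...) {
  tibble(
    k = x$k,
    n_features = length(x$features),
    stability = within_cluster_consensus(x$consensus$consensus, x$labels),
    kmeans_agreement = x$kmeans_agreement,
    weak_structure = x$weak_structure,
    fs_converged = x$fs_converged
  )
}

#' Identify the most aberrant subgroup
#'
#' The poor-prognosis candidate ("group B") is taken to be the subgroup
#' whose tumors deviate most, on average, from the adjacent-tissue profile
#' over the subgroup-defining features — the subgroup that differs from
#' normal tissue at the full feature set.
#'
#' @param beta A [beta_matrix] with both tissue roles.
#' @param labels Named subgroup labels of the tumor samples.
#' @param features Subgroup-defining probe ids.
#' @return The label (same type as `labels`) of the most aberrant subgroup.
#' @export
identify_group_b <- function(beta, labels, features) {
  features <- intersect(features, rownames(beta$values))
  adj_mean <- rowMeans(adjacent_values(beta)[features, , drop = FALSE],
                       na.rm = TRUE)
  tum <- tumor_values(beta)[features, names(labels), drop = FALSE]
  dev <- colMeans(abs(tum - adj_mean), na.rm = TRUE)
  by_group <- tapply(dev, labels[colnames(tum)], mean)
  names(by_group)[which.max(by_group)]
}

#' Overlap of subgroup-defining features with differential probes
#'
#' @param features Subgroup-defining probe ids.
#' @param diff A `diffmeth_result` on the same probe universe.
#' @return A one-row tibble: feature count, overlap count and fraction.
#' @export
overlap_with_diffmeth <- function(features, diff) {
  sig <- diff$probe_id[diff$significant]
  n_overlap <- length(intersect(features, sig))
  tibble(n_features = length(features), n_overlap = n_overlap,
         fraction = if (length(features) > 0) {
           n_overlap / length(features)
         } else {
           NA_real_
         })
}
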