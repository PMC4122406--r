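#' Merge two expression platforms by accession
#'
#' Restricts both platforms to accessions present on each, keeps every
#' probe of a shared accession (collapse to one probe per gene happens at
#' the differential-expression stage), and concatenates the samples with
#' their platform labels.
#'
#' @param a,b [expr_matrix] objects with accession maps.
#' @return A merged [expr_matrix]; accessions dropped from either side are
#'   recorded in attribute `dropped_accessions`.
#' @export
merge_platforms <- function(a, b) {
  acc_a <- a$feature_map$accession[match(rownames(a$values),
                                         a$feature_map$feature_id)]
  acc_b <- b$feature_map$accession[match(rownames(b$values),
                                         b$feature_map$feature_id)]
  shared <- intersect(acc_a, acc_b)
  if (length(shared) == 0) abort("No shared accessions between platforms.")
  keep_a <- acc_a %in% shared
  keep_b <- acc_b %in% shared
  va <- a$values[keep_a, , drop = FALSE]
  vb <- b$values[keep_b, , drop = FALSE]
  aligned <- align_by_accession(va, vb, acc_a[keep_a], acc_b[keep_b])
  meta <- dplyr::bind_rows(a$sample_meta, b$sample_meta)
  out <- expr_matrix(aligned$values, meta, aligned$map)
  attr(out, "dropped_accessions") <- setdiff(union(acc_a, acc_b), shared)
  out
}

# Pair platform-a probes with platform-b probes per accession so every
# output row is measured on all samples. When a platform has several probes
# for one accession, each is paired with the other platform's probes in
# order (recycling the last), keeping all probes tagged by origin.
align_by_accession <- function(va, vb, acc_a, acc_b) {
  rows <- list()
  map_rows <- list()
  for (acc in unique(acc_a)) {
    ia <- which(acc_a == acc)
    ib <- which(acc_b == acc)
    n_pair <- max(length(ia), length(ib))
    ia_rep <- rep_len(ia, n_pair)
    ib_rep <- rep_len(ib, n_pair)
    for (j in seq_len(n_pair)) {
      fid <- paste0(acc, if (n_pair > 1) paste0("#", j) else "")
      rows[[fid]] <- c(va[ia_rep[j], ], vb[ib_rep[j], ])
      map_rows[[fid]] <- tibble(
        feature_id = fid, accession = acc,
        probe_a = rownames(va)[ia_rep[j]], probe_b = rownames(vb)[ib_rep[j]]
      )
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- c(colnames(va), colnames(vb))
  list(values = values, map = dplyr::bind_rows(map_rows))
}

#' Parametric empirical-Bayes batch correction
#'
#' Removes per-gene platform (batch) location and scale effects while
#' preserving tissue-role effects: per-gene standardization against a
#' pooled model with the biological covariate retained, per-batch
#' location/scale estimation, shrinkage of both toward batch-level priors
#' (normal on locations, inverse-gamma on scales, hyperparameters by
#' moments, iterated to convergence), then adjustment and
#' back-transformation.
#'
#' @param x An [expr_matrix] whose `sample_meta$platform` defines the
#'   batches.
#' @param covariate Name of the biological covariate column in
#'   `sample_meta` to preserve (default `"role"`).
#' @return A list with `corrected` (an [expr_matrix]) and `model` (per-gene
#'   batch effect estimates before/after shrinkage and the prior
#'   hyperparameters).
#' @export
combat_correct <- function(x, covariate = "role") {
  batch <- factor(x$sample_meta$platform)
  n_batches <- table(batch)
  if (nlevels(batch) == 1) {
    return(list(corrected = x,
                model = list(note = "single batch; no correction applied")))
  }
  if (any(n_batches < 2)) abort("Every batch needs >= 2 samples.")
  dat <- x$values
  n_array <- ncol(dat)

  batchmod <- stats::model.matrix(~ -1 + batch)
  mod <- stats::model.matrix(~ factor(x$sample_meta[[covariate]]))
  design <- cbind(batchmod, mod)
  design <- design[, !apply(design, 2, function(v) all(v == 1)), drop = FALSE]

  nb <- nlevels(batch)
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(as.numeric(n_batches) / n_array,
                          B_hat[seq_len(nb), , drop = FALSE])
  var_pooled <- ((dat - t(design %*% B_hat))^2) %*% rep(1 / n_array, n_array)

  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  if (ncol(design) > nb) {
    tmp <- design
    tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / (sqrt(var_pooled) %*% t(rep(1, n_array)))

  gamma_hat <- t(solve(crossprod(batchmod), t(batchmod) %*% t(s_data)))
  delta_hat <- sapply(levels(batch), function(b) {
    apply(s_data[, batch == b, drop = FALSE], 1, stats::var)
  })

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); v <- stats::var(d); (2 * v + m^2) / v
  })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); v <- stats::var(d); (m * v + m^3) / v
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    sel <- batch == levels(batch)[i]
    nbi <- sum(sel)
    g_old <- gamma_hat[, i]
    d_old <- delta_hat[, i]
    change <- 1
    count <- 0
    while (change > 1e-4 && count < 500) {
      g_new <- (t2[i] * nbi * gamma_hat[, i] + d_old * gamma_bar[i]) /
        (t2[i] * nbi + d_old)
      sum2 <- rowSums((s_data[, sel, drop = FALSE] - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (nbi / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      count <- count + 1
    }
    gamma_star[, i] <- g_old
    delta_star[, i] <- d_old
  }

  bayes <- s_data
  for (i in seq_len(nb)) {
    sel <- batch == levels(batch)[i]
    bayes[, sel] <- (s_data[, sel, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  corrected <- bayes * (sqrt(var_pooled) %*% t(rep(1, n_array))) + stand_mean

  model <- list(
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, t2 = t2,
    a_prior = a_prior, b_prior = b_prior,
    batches = levels(batch)
  )
  list(corrected = expr_matrix(corrected, x$sample_meta, x$feature_map),
       model = model)
}

#' Before/after batch-correction quality report
#'
#' Principal-component coordinates of the samples before and after
#' correction, plus the squared correlation of any duplicate sample pairs
#' profiled on both platforms.
#'
#' @param x_before,x_after [expr_matrix] objects on the same features and
#'   samples.
#' @param duplicate_pairs Optional two-column data frame of sample-id pairs.
#' @return A list with `pca` (tibble: sample, platform, stage, PC1, PC2)
#'   and `duplicates` (tibble: sample_1, sample_2, r_squared).
#' @export
quality_batch_report <- function(x_before, x_after, duplicate_pairs = NULL) {
  pc_tbl <- function(x, stage) {
    p <- stats::prcomp(t(x$values), rank. = 2, scale. = FALSE)
    tibble(sample = colnames(x$values),
           platform = x$sample_meta$platform, stage = stage,
           PC1 = p$x[, 1], PC2 = p$x[, 2])
  }
  pca <- dplyr::bind_rows(pc_tbl(x_before, "before"), pc_tbl(x_after, "after"))
  dups <- if (is.null(duplicate_pairs) || nrow(duplicate_pairs) == 0) {
    tibble(sample_1 = character(), sample_2 = character(),
           r_squared = numeric())
  } else {
    purrr::map_dfr(seq_len(nrow(duplicate_pairs)), function(i) {
      s1 <- duplicate_pairs[[1]][i]
      s2 <- duplicate_pairs[[2]][i]
      tibble(sample_1 = s1, sample_2 = s2,
             r_squared = stats::cor(x_after$values[, s1],
                                    x_after$values[, s2])^2)
    })
  }
  list(pca = pca, duplicates = dups)
}

#' Differential expression between tumor and adjacent tissue
#'
#' Moderated t per feature, Benjamini-Hochberg control, significance at
#' `q < q_max` together with an anti-logged fold change strictly above
#' `min_fc`; for accessions with several probes the most significant probe
#' (smallest p) represents the gene.
#'
#' @param x An [expr_matrix] with both tissue roles.
#' @param q_max FDR threshold.
#' @param min_fc Minimum absolute fold change on the natural scale
#'   (`|logFC| > log2(min_fc)`).
#' @return A tibble with one row per accession: `accession`, `feature`,
#'   `logfc`, `fc`, `statistic`, `p`, `q`, `significant`, `direction`
#'   (`up`/`down`/`none`).
#' @export
differential_expression <- function(x, q_max = 0.05, min_fc = 1.2) {
  roles <- x$sample_meta$role
  if (!all(c("tumor", "adjacent") %in% roles)) {
    abort("Both tumor and adjacent samples are required.")
  }
  groups <- factor(roles, levels = c("adjacent", "tumor"))
  res <- moderated_t(x$values, groups)
  acc <- x$feature_map$accession[match(res$feature, x$feature_map$feature_id)]
  res$accession <- acc
  res |>
    dplyr::group_by(.data$accession) |>
    dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      accession = .data$accession, feature = .data$feature,
      logfc = .data$effect, fc = 2^.data$effect,
      statistic = .data$statistic, p = .data$p, q = .data$q,
      significant = .data$q < q_max & abs(.data$effect) > log2(min_fc),
      direction = dplyr::case_when(
        .data$significant & .data$effect > 0 ~ "up",
        .data$significant ~ "down",
        .default = "none"
      )
    )
}

#' Integrate differential methylation with differential expression
#'
#' Joins the two call sets by gene, assigns each doubly significant gene to
#' a starburst quadrant (hyper/hypo x up/down), and computes the Pearson
#' correlation between the gene's probe beta-values and its expression
#' across matched tumor samples. When a gene has several significant CpG
#' probes the one with the smallest methylation q represents it.
#'
#' @param diff_meth A `diffmeth_result`.
#' @param diff_expr Output of [differential_expression()].
#' @param ann Probe annotation providing the probe-to-gene map.
#' @param beta A [beta_matrix] (tumor columns used for correlation).
#' @param expr An [expr_matrix] (tumor columns used for correlation).
#' @return An `integrated_genes` tibble: `gene`, `probe_id`, `delta_beta`,
#'   `meth_q`, `logfc`, `expr_q`, `pearson_r`, `quadrant`
#'   (`hyper-down`, `hyper-up`, `hypo-down`, `hypo-up`, `ns`).
#' @export
integrate_meth_expr <- function(diff_meth, diff_expr, ann, beta, expr) {
  meth <- as_tibble(diff_meth) |>
    dplyr::mutate(gene = ann$gene[match(.data$probe_id, ann$probe_id)]) |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  joined <- dplyr::inner_join(
    meth |>
      dplyr::select(gene = "gene", probe_id = "probe_id",
                    delta_beta = "delta_beta", meth_q = "q",
                    meth_direction = "direction"),
    diff_expr |>
      dplyr::select(gene = "accession", expr_feature = "feature",
                    logfc = "logfc", expr_q = "q",
                    expr_direction = "direction"),
    by = "gene"
  )

  tum_b <- beta$sample_meta$sample[beta$sample_meta$role == "tumor"]
  tum_e <- expr$sample_meta$sample[expr$sample_meta$role == "tumor"]
  pat_b <- beta$sample_meta$patient[match(tum_b, beta$sample_meta$sample)]
  pat_e <- expr$sample_meta$patient[match(tum_e, expr$sample_meta$sample)]
  common <- intersect(pat_b, pat_e)
  bcols <- tum_b[match(common, pat_b)]
  ecols <- tum_e[match(common, pat_e)]

  joined$pearson_r <- purrr::map2_dbl(
    joined$probe_id, joined$expr_feature,
    function(pid, fid) {
      if (!pid %in% rownames(beta$values) ||
          !fid %in% rownames(expr$values)) {
        return(NA_real_)
      }
      suppressWarnings(stats::cor(beta$values[pid, bcols],
                                  expr$values[fid, ecols],
                                  use = "pairwise.complete.obs"))
    }
  )

  out <- joined |>
    dplyr::mutate(
      quadrant = dplyr::case_when(
        .data$meth_direction == "hyper" & .data$expr_direction == "down" ~ "hyper-down",
        .data$meth_direction == "hyper" & .data$expr_direction == "up" ~ "hyper-up",
        .data$meth_direction == "hypo" & .data$expr_direction == "down" ~ "hypo-down",
        .data$meth_direction == "hypo" & .data$expr_direction == "up" ~ "hypo-up",
        .default = "ns"
      )
    ) |>
    dplyr::select("gene", "probe_id", "delta_beta", "meth_q", "logfc",
                  "expr_q", "pearson_r", "quadrant")
  class(out) <- c("integrated_genes", class(out))
  out
}

#' Quadrant and correlation summary of an integration table
#'
#' @param x An `integrated_genes` tibble.
#' @param ... Unused.
#' @return A one-row tibble: genes joined, doubly significant count, counts
#'   per quadrant, and the inverse/positive correlation split among doubly
#'   significant genes.
#' @export
glance.integrated_genes <- function(x, ...) {
  sig <- x[x$quadrant != "ns", ]
  tibble(
    n_genes = nrow(x),
    n_integrated = nrow(sig),
    n_hyper_down = sum(sig$quadrant == "hyper-down"),
    n_hyper_up = sum(sig$quadrant == "hyper-up"),
    n_hypo_down = sum(sig$quadrant == "hypo-down"),
    n_hypo_up = sum(sig$quadrant == "hypo-up"),
    frac_inverse = ifelse(nrow(sig) > 0,
                          mean(sig$pearson_r < 0, na.rm = TRUE), NA_real_)
  )
}

#' Starburst coordinates
#'
#' Signed `-log10 q` on both axes: methylation on x (sign of delta-beta),
#' expression on y (sign of logFC).
#'
#' @param x An `integrated_genes` tibble.
#' @return A tibble with `gene`, `x`, `y`, `quadrant`.
#' @export
starburst_table <- function(x) {
  out <- tibble(gene = x$gene, quadrant = x$quadrant)
  out$x <- sign(x$delta_beta) * -log10(pmax(x$meth_q, 1e-300))
  out$y <- sign(x$logfc) * -log10(pmax(x$expr_q, 1e-300))
  out[, c("gene", "x", "y", "quadrant")]
}
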