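test_that("variable-probe selection ranks by SD with deterministic ties", {
  set.seed(31)
  vals <- matrix(runif(100 * 6), 100, 6,
                 dimnames = list(sprintf("cg%03d", 1:100), paste0("s", 1:6)))
  vals[7, ] <- 0.5                       # constant probe
  expect_equal(length(select_variable_probes(vals, 0.05)), 5L)
  expect_setequal(select_variable_probes(vals, 1), rownames(vals))
  expect_false("cg007" %in% select_variable_probes(vals, 0.5))
})

test_that("base clusterers separate well-separated blobs", {
  pb <- profile_blobs(20, 2, n_feat = 10, effect = 4, seed = 33)
  blob <- pb$x
  truth <- pb$labels
  for (m in c("hierarchical", "kmeans")) {
    lab <- base_cluster(blob, 2, method = m)
    expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  }
  # k = n gives singletons under hierarchical clustering
  lab_n <- base_cluster(blob[1:6, ], 6, method = "hierarchical")
  expect_equal(length(unique(lab_n)), 6L)
  # duplicated samples are always co-assigned
  dup <- blob[c(1, 1, 25, 30), ]
  rownames(dup) <- paste0("d", 1:4)
  lab_d <- base_cluster(dup, 2, method = "hierarchical")
  expect_equal(unname(lab_d[1]), unname(lab_d[2]))
  expect_error(base_cluster(blob, 1), ">= 2")
})

test_that("consensus matrix equals the brute-force counting oracle", {
  data <- profile_blobs(3, 2, n_feat = 8, effect = 3, seed = 35)$x
  for (sd_seed in c(1L, 2L, 3L)) {
    cm <- consensus_matrix(data, k = 2, n_iter = 5, subsample = 0.8,
                           seed = sd_seed)
    oracle <- brute_consensus(data, k = 2, n_iter = 5, subsample = 0.8,
                              seed = sd_seed)
    expect_equal(unname(cm$consensus), unname(oracle), tolerance = 1e-12)
    expect_true(all(cm$cosampled <= 5))
  }
})

test_that("consensus matrix properties hold", {
  data <- profile_blobs(6, 3, n_feat = 12, effect = 4, seed = 37)$x
  cm <- consensus_matrix(data, k = 3, n_iter = 100, subsample = 0.8,
                         seed = 5)
  C <- cm$consensus
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 18))
  expect_true(all(C >= 0 & C <= 1))

  # full subsample with a deterministic base gives a binary matrix
  cm1 <- consensus_matrix(data, k = 3, n_iter = 7, subsample = 1, seed = 5)
  expect_true(all(cm1$consensus %in% c(0, 1)))

  # three planted groups: near-binary block structure
  truth <- rep(1:3, each = 6)
  within <- C[outer(truth, truth, "==") & upper.tri(C)]
  between <- C[outer(truth, truth, "!=") & upper.tri(C)]
  expect_gte(mean(within), 0.95)
  expect_lte(mean(between), 0.05)

  # scale invariance of the hierarchical base (Pearson distance)
  cm_scaled <- consensus_matrix(data * 7, k = 3, n_iter = 100,
                                subsample = 0.8, seed = 5)
  expect_equal(cm_scaled$consensus, C)
})

test_that("cut_consensus recovers block labels, also under noise", {
  blocks <- rep(1:3, times = c(5, 6, 7))
  n <- length(blocks)
  C <- outer(blocks, blocks, function(a, b) as.numeric(a == b))
  dimnames(C) <- list(paste0("s", 1:n), paste0("s", 1:n))
  lab <- cut_consensus(C, 3)
  expect_equal(mclust::adjustedRandIndex(lab, blocks), 1)

  # permutation equivariance
  perm <- sample(n)
  lab_p <- cut_consensus(C[perm, perm], 3)
  expect_equal(mclust::adjustedRandIndex(lab_p, blocks[perm]), 1)

  # noisy blocks
  set.seed(39)
  ok <- vapply(1:20, function(i) {
    N <- matrix(rnorm(n * n, 0, 0.1), n, n)
    N <- (N + t(N)) / 2
    Cn <- pmin(pmax(C + N, 0), 1)
    diag(Cn) <- 1
    dimnames(Cn) <- dimnames(C)
    mclust::adjustedRandIndex(cut_consensus(Cn, 3), blocks)
  }, numeric(1))
  expect_gte(mean(ok >= 0.9), 0.95)
})

test_that("choose_k finds planted structure and degrades gracefully", {
  data <- profile_blobs(8, 3, n_feat = 12, effect = 3, seed = 41)$x
  cms <- lapply(2:5, function(k) {
    consensus_matrix(data, k = k, n_iter = 100, subsample = 0.8,
                     seed = 100 + k)
  })
  sel <- choose_k(cms)
  expect_equal(sel$k, 3L)
  expect_true(all(sel$trace$delta_area >= 0))

  # k_max = 2: only one candidate pair -> returns 2
  sel2 <- choose_k(cms[1:2])
  expect_true(sel2$k %in% 2:3)

  # structureless data flags weak structure
  set.seed(9)
  noise <- matrix(rnorm(24 * 12), 24, 12,
                  dimnames = list(paste0("s", 1:24), NULL))
  cms_n <- lapply(2:5, function(k) {
    consensus_matrix(noise, k = k, n_iter = 100, subsample = 0.8,
                     seed = 200 + k)
  })
  sel_n <- choose_k(cms_n)
  expect_true(sel_n$weak_structure)
})

test_that("feature selection retains markers and calibrates under null labels", {
  cfg <- cohort_config(n_patients = 30, subgroup_sizes = c(10, 10, 10),
                       n_probes = 1000, seed = 43)
  cohort <- simulate_cohort(cfg)
  tum <- tumor_values(cohort$beta)
  truth <- cohort$truth$subgroup
  markers <- cohort$truth$marker_probes$probe_id
  # universe: markers plus background noise probes
  universe <- unique(c(markers, sample(rownames(tum), 300)))
  labels <- truth[sub("T$", "", colnames(tum))]
  names(labels) <- colnames(tum)
  fs <- feature_select_iterate(tum[universe, ], labels, fdr = 0.05,
                               n_iter = 100, seed = 7)
  expect_gte(mean(markers %in% fs$features), 0.95)
  final_ari <- mclust::adjustedRandIndex(fs$labels[colnames(tum)], labels)
  expect_equal(final_ari, 1)
  expect_true(all(diff(fs$trace$stability) >= -1e-9))

  # random labels keep roughly fdr * n features
  set.seed(45)
  null_tum <- tum[sample(rownames(tum), 400), ]
  rand_labels <- stats::setNames(sample(rep(1:3, each = 10)), colnames(tum))
  mf <- moderated_f(null_tum, rand_labels[colnames(null_tum)])
  n_kept <- sum(mf$q < 0.5)  # BH at a loose threshold on null data
  expect_lte(n_kept, 0.5 * 400 + 3 * sqrt(400 * 0.5 * 0.5))
})

test_that("feature selection converges to a fixed point on stable features", {
  cfg <- cohort_config(n_patients = 24, subgroup_sizes = c(8, 8, 8),
                       n_probes = 400, frac_subgroup_probes = 0.25,
                       seed = 47)
  cohort <- simulate_cohort(cfg)
  tum <- tumor_values(cohort$beta)
  markers <- cohort$truth$marker_probes$probe_id
  labels <- cohort$truth$subgroup[sub("T$", "", colnames(tum))]
  names(labels) <- colnames(tum)
  fs <- feature_select_iterate(tum[markers, ], labels, fdr = 0.05,
                               n_iter = 100, seed = 9, max_rounds = 5)
  expect_true(fs$converged)
  # the discriminating markers are a fixed point (markers whose planted
  # shift was clipped near the beta ceiling carry almost no signal and may
  # legitimately drop out in round one)
  expect_gte(mean(markers %in% fs$features), 0.9)
  expect_true(all(fs$features %in% markers))
})

test_that("the full CHC-FS pipeline recovers planted subgroups deterministically", {
  cfg <- cohort_config(n_patients = 30, subgroup_sizes = c(10, 10, 10),
                       n_probes = 1500, seed = 49)
  cohort <- simulate_cohort(cfg)
  res <- chcfs(cohort$beta, n_iter = 150, k_max = 4, seed = 3)
  truth <- cohort$truth$subgroup
  lab <- res$labels
  expect_equal(res$k, 3L)
  expect_gte(mclust::adjustedRandIndex(lab, truth[sub("T$", "", names(lab))]),
             0.9)
  expect_gte(res$kmeans_agreement, 0.8)

  # determinism
  res2 <- chcfs(cohort$beta, n_iter = 150, k_max = 4, seed = 3)
  expect_identical(res2$labels, res$labels)
  expect_identical(res2$features, res$features)

  # tidy/glance interfaces
  td <- tidy(res)
  expect_setequal(td$sample, names(lab))
  expect_equal(glance(res)$k, 3L)
})

test_that("single-subgroup data is flagged as weak structure", {
  cfg <- cohort_config(n_patients = 24, subgroup_sizes = c(22, 1, 1),
                       n_probes = 800, frac_subgroup_probes = 0,
                       seed = 51)
  cohort <- simulate_cohort(cfg)
  res <- chcfs(cohort$beta, n_iter = 100, k_max = 4, seed = 5, fdr = 0.9,
               run_kmeans = FALSE)
  expect_true(res$weak_structure)
})

test_that("feature overlap against differential methylation is a plain fraction", {
  diff <- tibble::tibble(probe_id = sprintf("cg%03d", 1:199),
                         significant = c(rep(TRUE, 170), rep(FALSE, 29)))
  ov <- overlap_with_diffmeth(diff$probe_id, diff)
  expect_equal(ov$fraction, 170 / 199, tolerance = 1e-12)
  expect_equal(overlap_with_diffmeth(c("x", "y"), diff)$fraction, 0)
  expect_equal(overlap_with_diffmeth(sprintf("cg%03d", 1:170), diff)$fraction, 1)
})
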