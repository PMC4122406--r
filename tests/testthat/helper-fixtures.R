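# Small cohorts used across tests: reduced probe counts keep the unit suite
# fast; tests that exercise the study-scale conditions build their own.

tiny_cfg <- function(...) {
  cohort_config(n_patients = 12L, subgroup_sizes = c(4L, 4L, 4L),
                n_probes = 400L, seed = 101L, ...)
}

null_cfg <- function(n_probes = 2000L, seed = 202L) {
  cohort_config(n_probes = n_probes, frac_diff_probes = 0,
                frac_subgroup_probes = 0, seed = seed)
}

# Hand-built 3-probe beta matrix with paired samples for IO tests.
toy_beta <- function() {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4,
                   0.5, 0.6, 0.7, 0.8,
                   0.15, 0.25, 0.35, 0.45),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("cg", 1:3),
                                 c("P1T", "P2T", "P1N", "P2N")))
  beta_matrix(vals, tibble::tibble(
    sample = colnames(vals),
    patient = c("P1", "P2", "P1", "P2"),
    role = c("tumor", "tumor", "adjacent", "adjacent")
  ))
}

# Groups that differ in feature *profile* (block-elevated features), the
# structure Pearson-distance clustering responds to; flat mean shifts are
# invisible to correlation distances.
profile_blobs <- function(n_per, k, n_feat = 12, effect = 3, sd = 1,
                          seed = 1) {
  withr::with_seed(as.integer(seed), {
    lab <- rep(seq_len(k), each = n_per)
    blocks <- split(seq_len(n_feat),
                    cut(seq_len(n_feat), k, labels = FALSE))
    centers <- matrix(0, k, n_feat)
    for (g in seq_len(k)) centers[g, blocks[[g]]] <- effect
    x <- centers[lab, , drop = FALSE] +
      matrix(stats::rnorm(length(lab) * n_feat, 0, sd), ncol = n_feat)
    rownames(x) <- paste0("s", seq_along(lab))
    list(x = x, labels = lab)
  })
}

# Brute-force consensus counting: re-runs the same subsample draws as
# consensus_matrix() and tallies co-cluster / co-sample counts directly.
brute_consensus <- function(data, k, n_iter, subsample, seed) {
  n <- nrow(data)
  m <- ceiling(subsample * n)
  together <- matrix(0, n, n)
  cosampled <- matrix(0, n, n)
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(n_iter)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      labels <- base_cluster(data[idx, , drop = FALSE], k = k,
                             method = "hierarchical")
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          i <- idx[a]; j <- idx[b]
          cosampled[i, j] <- cosampled[i, j] + 1
          if (labels[a] == labels[b]) together[i, j] <- together[i, j] + 1
        }
      }
    }
  })
  C <- together / cosampled
  C[cosampled == 0] <- 0
  diag(C) <- 1
  C
}
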