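make_two_platform <- function(seed = 61, n_genes = 400, shift_sd = 0.8,
                              scale = 1.5) {
  cohort_cfg <- cohort_config(n_patients = 30,
                              subgroup_sizes = c(10, 10, 10),
                              n_probes = round(n_genes * 1.9),
                              batch_shift = shift_sd, batch_scale = scale,
                              seed = seed)
  simulate_cohort(cohort_cfg)
}

test_that("platform merging keeps only shared accessions", {
  co <- make_two_platform()
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  expect_setequal(colnames(merged$values),
                  c(colnames(co$expr$platform_a$values),
                    colnames(co$expr$platform_b$values)))

  # hand fixture: 5 vs 3 accessions, 3 shared
  mk <- function(genes, samples, platform) {
    v <- matrix(rnorm(length(genes) * length(samples)),
                length(genes), length(samples),
                dimnames = list(paste0(platform, "_", genes), samples))
    expr_matrix(v, tibble::tibble(sample = samples, patient = samples,
                                  role = "tumor", platform = platform),
                tibble::tibble(feature_id = rownames(v), accession = genes))
  }
  a <- mk(paste0("g", 1:5), c("s1", "s2"), "pa")
  b <- mk(paste0("g", 3:5), c("s3", "s4"), "pb")
  m <- merge_platforms(a, b)
  expect_equal(nrow(m$values), 3L)
  expect_setequal(attr(m, "dropped_accessions"), c("g1", "g2"))
  expect_error(merge_platforms(mk("x", "s1", "pa"), mk("y", "s2", "pb")),
               "shared")

  # identical platforms: merge is column concatenation
  b2 <- mk(paste0("g", 1:5), c("s5", "s6"), "pb")
  m2 <- merge_platforms(a, b2)
  expect_equal(dim(m2$values), c(5L, 4L))
})

test_that("batch correction matches the reference implementation exactly", {
  co <- make_two_platform()
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  cc <- combat_correct(merged)
  mod <- stats::model.matrix(~ factor(merged$sample_meta$role))
  ref <- suppressMessages(
    sva::ComBat(dat = merged$values, batch = merged$sample_meta$platform,
                mod = mod)
  )
  expect_equal(cc$corrected$values, ref, tolerance = 1e-10)
  expect_true(all(cc$model$delta_star > 0))
})

test_that("batch correction removes planted shifts and preserves effects", {
  co <- make_two_platform(seed = 63)
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  cc <- combat_correct(merged)
  b1 <- merged$sample_meta$platform == "agilent_like"
  signal_genes <- c(co$truth$coupled_genes$gene, co$truth$de_genes$gene)
  null_genes <- setdiff(rownames(merged$values), signal_genes)
  d_before <- rowMeans(merged$values[null_genes, b1]) -
    rowMeans(merged$values[null_genes, !b1])
  d_after <- rowMeans(cc$corrected$values[null_genes, b1]) -
    rowMeans(cc$corrected$values[null_genes, !b1])
  expect_lt(stats::sd(d_after), 0.1 * stats::sd(d_before))

  # tumor effects survive correction: the post-correction logFC stays at
  # the pre-correction value (batches are role-balanced, so the raw logFC
  # is the unbiased benchmark at this cohort size)
  de <- co$truth$de_genes
  tum <- merged$sample_meta$role == "tumor"
  fc_before <- rowMeans(merged$values[de$gene, tum]) -
    rowMeans(merged$values[de$gene, !tum])
  fc_after <- rowMeans(cc$corrected$values[de$gene, tum]) -
    rowMeans(cc$corrected$values[de$gene, !tum])
  expect_lt(mean(abs(fc_after - fc_before)), 0.1)
  expect_gt(stats::cor(fc_after, de$logfc), 0.9)
})

test_that("re-correction is a contraction, not a large perturbation", {
  co <- make_two_platform(seed = 65)
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  once <- combat_correct(merged)$corrected
  twice <- combat_correct(once)$corrected
  delta <- mean(abs(twice$values - once$values))
  expect_lt(delta, 0.05)
  b1 <- merged$sample_meta$platform == "agilent_like"
  resid1 <- rowMeans(once$values[, b1]) - rowMeans(once$values[, !b1])
  resid2 <- rowMeans(twice$values[, b1]) - rowMeans(twice$values[, !b1])
  expect_lte(stats::sd(resid2), stats::sd(resid1) + 1e-8)
})

test_that("single-batch input is returned unchanged", {
  co <- make_two_platform()
  a <- co$expr$platform_a
  cc <- combat_correct(a)
  expect_equal(cc$corrected$values, a$values, tolerance = 1e-10)
})

test_that("quality report covers PCA and duplicate concordance", {
  co <- make_two_platform()
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  cc <- combat_correct(merged)
  dup <- merged
  rep <- quality_batch_report(merged, cc$corrected,
                              tibble::tibble(s1 = colnames(merged$values)[1],
                                             s2 = colnames(merged$values)[1]))
  expect_equal(nrow(rep$duplicates), 1L)
  expect_equal(rep$duplicates$r_squared, 1)
  expect_setequal(unique(rep$pca$stage), c("before", "after"))
  rep0 <- quality_batch_report(merged, cc$corrected)
  expect_equal(nrow(rep0$duplicates), 0L)
})

test_that("differential expression applies strict fold-change and collapse rules", {
  co <- make_two_platform(seed = 67)
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  cc <- combat_correct(merged)
  de <- differential_expression(cc$corrected)
  expect_false(any(duplicated(de$accession)))
  # strictly: logFC just under log2(1.2) is never significant
  expect_false(any(de$significant & abs(de$logfc) <= log2(1.2)))

  # most-significant-probe collapse on a hand fixture
  v <- rbind(p1 = c(8, 8, 8.1, 9.2, 9.1, 9.3),
             p2 = c(8, 8.1, 8, 10.5, 10.4, 10.6),
             q1 = c(7, 7, 7.1, 7.05, 7.04, 7.06))
  colnames(v) <- paste0("s", 1:6)
  x <- expr_matrix(v, tibble::tibble(
    sample = colnames(v), patient = colnames(v),
    role = rep(c("adjacent", "tumor"), each = 3), platform = "pa"),
    tibble::tibble(feature_id = c("p1", "p2", "q1"),
                   accession = c("geneA", "geneA", "geneB")))
  de2 <- differential_expression(x)
  expect_equal(de2$feature[de2$accession == "geneA"], "p2")
})

test_that("null expression cohorts stay below the nominal false-call rate", {
  cfg <- cohort_config(n_probes = 2000, frac_diff_probes = 0,
                       frac_subgroup_probes = 0, expr_de_frac = 0,
                       seed = 69)
  co <- simulate_cohort(cfg)
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  de <- differential_expression(combat_correct(merged)$corrected)
  expect_lte(mean(de$significant), 0.01)
})

test_that("integration assigns quadrants and recovers planted inverse coupling", {
  cfg <- cohort_config(seed = 71)
  co <- simulate_cohort(cfg)
  diffm <- differential_methylation(co$beta)
  merged <- merge_platforms(co$expr$platform_a, co$expr$platform_b)
  cc <- combat_correct(merged)
  de <- differential_expression(cc$corrected)
  integ <- integrate_meth_expr(diffm, de, co$annotation, co$beta,
                               cc$corrected)
  g <- glance(integ)
  expect_equal(g$n_hyper_down + g$n_hyper_up + g$n_hypo_down + g$n_hypo_up,
               g$n_integrated)

  # planted inverse-coupled genes: hyper-down / hypo-up with r < 0
  inv <- co$truth$coupled_genes[co$truth$coupled_genes$slope < 0, ]
  found <- integ[integ$gene %in% inv$gene & integ$quadrant != "ns", ]
  expect_gt(nrow(found), 0.5 * nrow(inv))
  ok <- found$quadrant %in% c("hyper-down", "hypo-up") & found$pearson_r < 0
  expect_gte(mean(ok), 0.9)

  # join-order invariance of quadrants
  integ2 <- integrate_meth_expr(diffm[sample(nrow(diffm)), ], de,
                                co$annotation, co$beta, cc$corrected)
  both <- dplyr::inner_join(integ, integ2, by = "gene")
  expect_equal(both$quadrant.x, both$quadrant.y)

  sb <- starburst_table(integ)
  expect_equal(nrow(sb), nrow(integ))
  expect_true(all(sign(sb$x[integ$quadrant == "hyper-down"]) > 0))
  expect_true(all(sign(sb$y[integ$quadrant == "hyper-down"]) < 0))
})
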