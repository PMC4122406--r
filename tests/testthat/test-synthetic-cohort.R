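test_that("annotation respects chromosome and CGI configuration", {
  cfg <- cohort_config(seed = 5)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), cfg$n_probes)

  # zero sex fraction -> no sex-chromosome probes
  ann0 <- generate_annotation(cohort_config(sex_chr_fraction = 0, seed = 5))
  expect_false(any(ann0$chromosome %in% c("chrX", "chrY")))

  # boundary: everything CGI
  ann1 <- generate_annotation(cohort_config(cgi_fraction = 1, seed = 5))
  expect_true(all(ann1$cgi))

  # marginal CGI count behaves like binomial(n, cgi_fraction)
  n_cgi <- sum(ann$cgi)
  expect_lt(abs(n_cgi - cfg$n_probes * 0.7),
            3 * sqrt(cfg$n_probes * 0.7 * 0.3))

  # designated probes carry the island bias
  expect_gt(mean(ann$cgi[ann$designation == "hyper"]), 0.8)
  expect_lt(mean(ann$cgi[ann$designation == "hypo"]), 0.4)
})

test_that("methylation values honor the beta-value and pairing contract", {
  cfg <- tiny_cfg()
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  v <- meth$beta$values
  expect_true(all(v >= 0 & v <= 1))
  meta <- meth$beta$sample_meta
  # paired tumor and adjacent columns for every patient
  pairs <- table(meta$patient, meta$role)
  expect_true(all(pairs == 1))
})

test_that("planted differential effects have the configured size", {
  cfg <- cohort_config(seed = 7)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  tv <- tumor_values(meth$beta)
  av <- adjacent_values(meth$beta)
  hyper <- meth$truth$diff_probes$probe_id[
    meth$truth$diff_probes$direction == "hyper"]
  obs <- rowMeans(tv[hyper, ]) - rowMeans(av[hyper, ])
  expect_gt(length(hyper), 100)
  expect_lt(abs(mean(obs) - 0.25), 0.03)
})

test_that("a null cohort has no tumor/adjacent differences beyond noise", {
  cfg <- null_cfg()
  meth <- generate_methylation(cfg, generate_annotation(cfg))
  d <- abs(rowMeans(tumor_values(meth$beta)) -
             rowMeans(adjacent_values(meth$beta)))
  expect_gte(mean(d <= 0.05), 0.99)
})

test_that("expression batches partition the patients and plant inverse coupling", {
  cfg <- tiny_cfg()
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  expr <- generate_expression(cfg, meth, ann, split = 5L)
  pa <- unique(expr$platform_a$sample_meta$patient)
  pb <- unique(expr$platform_b$sample_meta$patient)
  expect_length(intersect(pa, pb), 0)
  expect_setequal(c(pa, pb), unique(meth$beta$sample_meta$patient))
  expect_gte(sum(expr$truth$coupled_genes$slope < 0), 1)
})

test_that("batch-free configuration leaves no platform effect", {
  cfg <- cohort_config(n_patients = 30, subgroup_sizes = c(10, 10, 10),
                       n_probes = 2000, batch_shift = 0, batch_scale = 1,
                       seed = 11)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  expr <- generate_expression(cfg, meth, ann, split = 15L)
  null_genes <- setdiff(rownames(expr$platform_a$values),
                        paste0("PA_", c(expr$truth$coupled_genes$gene,
                                        expr$truth$de_genes$gene)))
  a <- expr$platform_a$values[null_genes, , drop = FALSE]
  b <- expr$platform_b$values[sub("^PA_", "PB_", null_genes), , drop = FALSE]
  # per-gene two-sample t at alpha = 0.01 should reject at the nominal rate
  pvals <- vapply(seq_len(nrow(a)), function(i) {
    stats::t.test(a[i, ], b[i, ])$p.value
  }, numeric(1))
  expect_lte(mean(pvals < 0.01), 0.03)
})

test_that("survival generation follows the configured censoring and hazards", {
  cfg <- tiny_cfg(censor_rate = 0)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  surv <- generate_survival(cfg, meth$truth$subgroup, "OS")
  expect_true(all(surv$event))
  expect_true(all(surv$time > 0))

  # hr = 1 -> generalized Wilcoxon p approximately uniform over replicates
  pvals <- vapply(1:200, function(i) {
    cfgn <- cohort_config(n_patients = 30, subgroup_sizes = c(10, 10, 10),
                          n_probes = 10, hr_groupB = 1, seed = 5000 + i)
    grp <- sample(rep(1:3, each = 10))
    names(grp) <- sprintf("P%03d", 1:30)
    s <- generate_survival(cfgn, grp, "OS")
    s$ab <- ifelse(s$group == 2, "B", "A")
    gehan_wilcoxon(dplyr::rename(s, group_old = group, group = ab))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clinical covariates are independent of subgroup", {
  cfg <- cohort_config(seed = 31)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  surv <- generate_survival(cfg, meth$truth$subgroup, "OS")
  fa <- fisher_association(surv$group, surv[, c("hbv", "gender")])
  expect_true(all(fa$p > 0.001))
})

test_that("a written cohort round-trips through the readers", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(tiny_cfg())
  write_cohort(cohort, dir)
  beta2 <- read_beta_matrix(file.path(dir, "beta.tsv"),
                            file.path(dir, "samples.csv"))
  expect_equal(beta2$values, cohort$beta$values, tolerance = 1e-8)
  expect_equal(beta2$sample_meta$role, cohort$beta$sample_meta$role)
  ann2 <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann2$cgi, cohort$annotation$cgi)
  ea <- read_expr_matrix(file.path(dir, "expr_platform_a.tsv"),
                         file.path(dir, "expr_platform_a_samples.csv"),
                         file.path(dir, "expr_platform_a_map.tsv"))
  expect_equal(ea$values, cohort$expr$platform_a$values, tolerance = 1e-6)
})

test_that("generation is deterministic given the seed", {
  c1 <- simulate_cohort(tiny_cfg())
  c2 <- simulate_cohort(tiny_cfg())
  expect_identical(c1$beta$values, c2$beta$values)
  expect_identical(c1$truth$subgroup, c2$truth$subgroup)
  expect_identical(c1$expr$platform_b$values, c2$expr$platform_b$values)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(subgroup_sizes = c(10, 10, 10)),
               class = "methcluster_config_error")
  expect_error(cohort_config(frac_diff_probes = 1.5),
               class = "methcluster_config_error")
  expect_error(cohort_config(hr_groupB = -1),
               class = "methcluster_config_error")
})
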