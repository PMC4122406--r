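#' Pipeline configuration
#'
#' Bundles every stage threshold with either a simulation block or input
#' paths, an output directory and the master seed from which all stage
#' substreams derive.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param cohort A [cohort_config] for simulate-mode, or `NULL` to read
#'   `input` paths.
#' @param input Named list of paths (`beta`, `beta_meta`, `detp`,
#'   `annotation`, `expr_a`, `expr_a_meta`, `expr_a_map`, `expr_b`,
#'   `expr_b_meta`, `expr_b_map`, `survival`) when not simulating.
#' @param detection_alpha Detection p-value threshold.
#' @param q_max FDR threshold for differential methylation and expression.
#' @param min_delta Minimum absolute beta-difference.
#' @param min_fc Minimum absolute expression fold change.
#' @param variable_fraction Most-variable-probe fraction for clustering.
#' @param k_max,n_iter,subsample,fs_fdr Consensus-clustering parameters.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            input = NULL,
                            detection_alpha = 0.05,
                            q_max = 0.05,
                            min_delta = 0.1,
                            min_fc = 1.2,
                            variable_fraction = 0.05,
                            k_max = 5L,
                            n_iter = 1000L,
                            subsample = 0.8,
                            fs_fdr = 0.05,
                            seed = 1L) {
  check_fraction(detection_alpha, "detection_alpha")
  check_fraction(q_max, "q_max")
  check_fraction(subsample, "subsample", allow_zero = FALSE)
  check_fraction(variable_fraction, "variable_fraction", allow_zero = FALSE)
  if (min_fc < 1) abort("`min_fc` must be >= 1.",
                        class = "methcluster_config_error")
  structure(list(out_dir = out_dir, cohort = cohort, input = input,
                 detection_alpha = detection_alpha, q_max = q_max,
                 min_delta = min_delta, min_fc = min_fc,
                 variable_fraction = variable_fraction, k_max = k_max,
                 n_iter = n_iter, subsample = subsample, fs_fdr = fs_fdr,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the complete analysis pipeline
#'
#' Executes simulate (optional), preprocess, differential methylation,
#' CHC-FS clustering, expression integration and survival association in
#' sequence, writing every intermediate table under `config$out_dir` and
#' returning a machine-readable manifest of stage outputs and headline
#' counts.
#'
#' @param config A [pipeline_config].
#' @return The run manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  state <- list(config = config)

  stages <- c("simulate", "preprocess", "diffmeth", "cluster",
              "integrate", "survival")
  for (st in stages) {
    state <- tryCatch(
      switch(st,
             simulate = stage_simulate(state),
             preprocess = stage_preprocess(state),
             diffmeth = stage_diffmeth(state),
             cluster = stage_cluster(state),
             integrate = stage_integrate(state),
             survival = stage_survival(state)),
      error = function(e) {
        abort(sprintf("Stage '%s' failed: %s (last good artifacts in %s)",
                      st, conditionMessage(e), config$out_dir),
              parent = e)
      }
    )
    manifest$stages[[st]] <- state$last_summary
  }
  manifest$summary <- state$headline
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Individual pipeline stages
#'
#' Each stage consumes the state produced by the previous one (or reads
#' stage artifacts from disk when run standalone through [run_all()]) and
#' writes its own artifacts.
#'
#' @param state Pipeline state list carrying `config` and prior results.
#' @return The updated state.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(state) {
  cfg <- state$config
  if (is.null(cfg$cohort)) {
    inp <- cfg$input
    beta <- read_beta_matrix(inp$beta, inp$beta_meta)
    state$cohort <- list(
      beta = beta,
      detp = read_matrix_tsv(inp$detp, "detection p"),
      annotation = read_annotation(inp$annotation),
      expr = list(
        platform_a = read_expr_matrix(inp$expr_a, inp$expr_a_meta,
                                      inp$expr_a_map),
        platform_b = read_expr_matrix(inp$expr_b, inp$expr_b_meta,
                                      inp$expr_b_map)
      ),
      survival = readr::read_csv(inp$survival, show_col_types = FALSE),
      truth = NULL
    )
    state$last_summary <- list(mode = "read", n_probes = nrow(beta$values))
  } else {
    cohort_cfg <- cfg$cohort
    cohort_cfg$seed <- derive_seed(cfg$seed, 11L)
    class(cohort_cfg) <- "cohort_config"
    state$cohort <- simulate_cohort(cohort_cfg)
    sim_dir <- file.path(cfg$out_dir, "simulated")
    write_cohort(state$cohort, sim_dir)
    state$last_summary <- list(mode = "simulate",
                               n_probes = cohort_cfg$n_probes,
                               n_patients = cohort_cfg$n_patients)
  }
  state
}

#' @rdname pipeline_stages
#' @export
stage_preprocess <- function(state) {
  cfg <- state$config
  beta <- preprocess_beta(state$cohort$beta, state$cohort$detp,
                          state$cohort$annotation,
                          alpha = cfg$detection_alpha)
  write_beta_matrix(beta, file.path(cfg$out_dir, "beta_normalized.tsv"),
                    file.path(cfg$out_dir, "samples.csv"))
  state$beta <- beta
  state$last_summary <- list(
    n_probes_kept = nrow(beta$values),
    n_probes_dropped = nrow(attr(beta, "removal")),
    n_sex_removed = attr(beta, "n_sex_removed")
  )
  state
}

#' @rdname pipeline_stages
#' @export
stage_diffmeth <- function(state) {
  cfg <- state$config
  diff <- differential_methylation(state$beta, q_max = cfg$q_max,
                                   min_delta = cfg$min_delta)
  enr <- cgi_enrichment(diff, state$cohort$annotation)
  readr::write_tsv(as_tibble(diff), file.path(cfg$out_dir, "diffmeth.tsv"))
  jsonlite::write_json(enr, file.path(cfg$out_dir, "cgi_enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  state$diffmeth <- diff
  state$cgi <- enr
  state$last_summary <- as.list(glance(diff))
  state
}

#' @rdname pipeline_stages
#' @export
stage_cluster <- function(state) {
  cfg <- state$config
  res <- chcfs(state$beta, variable_fraction = cfg$variable_fraction,
               k_max = cfg$k_max, n_iter = cfg$n_iter,
               subsample = cfg$subsample, fdr = cfg$fs_fdr,
               seed = derive_seed(cfg$seed, 12L))
  readr::write_tsv(tidy(res), file.path(cfg$out_dir, "subgroups.tsv"))
  readr::write_tsv(tibble(probe_id = res$features),
                   file.path(cfg$out_dir, "cluster_features.tsv"))
  write_matrix_tsv(res$consensus$consensus,
                   file.path(cfg$out_dir, "consensus_matrix.tsv"))
  jsonlite::write_json(list(k_trace = res$k_trace, fs_trace = res$fs_trace),
                       file.path(cfg$out_dir, "cluster_trace.json"),
                       auto_unbox = TRUE, digits = NA)
  state$cluster <- res
  state$last_summary <- as.list(glance(res))
  state
}

#' @rdname pipeline_stages
#' @export
stage_integrate <- function(state) {
  cfg <- state$config
  merged <- merge_platforms(state$cohort$expr$platform_a,
                            state$cohort$expr$platform_b)
  corrected <- combat_correct(merged)$corrected
  de <- differential_expression(corrected, q_max = cfg$q_max,
                                min_fc = cfg$min_fc)
  integrated <- integrate_meth_expr(state$diffmeth, de,
                                    state$cohort$annotation,
                                    state$beta, corrected)
  readr::write_tsv(de, file.path(cfg$out_dir, "diffexpr.tsv"))
  readr::write_tsv(as_tibble(integrated),
                   file.path(cfg$out_dir, "integrated_genes.tsv"))
  readr::write_tsv(starburst_table(integrated),
                   file.path(cfg$out_dir, "starburst.tsv"))
  state$diffexpr <- de
  state$integrated <- integrated
  state$last_summary <- c(list(n_de_genes = sum(de$significant)),
                          as.list(glance(integrated)))
  state
}

#' @rdname pipeline_stages
#' @export
stage_survival <- function(state) {
  cfg <- state$config
  labels <- state$cluster$labels
  surv <- state$cohort$survival
  surv$group <- labels[paste0(surv$patient, "T")]
  b_label <- identify_group_b(state$beta, labels, state$cluster$features)
  surv$group_ab <- merge_groups(
    surv$group,
    merge_spec = list(A = setdiff(unique(surv$group), b_label),
                      B = b_label)
  )
  reports <- purrr::map(split(surv, surv$endpoint), function(d) {
    cox <- cox_univariate(d, "group_ab")
    gw3 <- tryCatch(gehan_wilcoxon(dplyr::mutate(d, group = .data$group_ab)),
                    error = function(e) tibble(chi2 = NA, p = NA))
    list(cox = as.list(cox), gehan_p = gw3$p[1])
  })
  clin_cols <- intersect(names(surv), unique(clinical_marginals()$parameter))
  fisher <- fisher_association(surv$group[surv$endpoint == "OS"],
                               surv[surv$endpoint == "OS", clin_cols])
  readr::write_csv(surv, file.path(cfg$out_dir, "survival_groups.csv"))
  jsonlite::write_json(list(survival = reports, fisher = fisher),
                       file.path(cfg$out_dir, "outcome_report.json"),
                       auto_unbox = TRUE, digits = NA)
  state$outcome <- reports
  state$last_summary <- list(
    os_hr = reports$OS$cox$hr, os_gehan_p = reports$OS$gehan_p,
    dfs_hr = if (!is.null(reports$DFS)) reports$DFS$cox$hr else NA
  )
  state$headline <- list(
    subgroup_sizes = as.list(table(labels)),
    n_diffmeth = sum(state$diffmeth$significant),
    n_features = length(state$cluster$features),
    k = state$cluster$k,
    os_hr = reports$OS$cox$hr
  )
  state
}

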