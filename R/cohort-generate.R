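#' Generate probe annotation for a synthetic array
#'
#' Assigns each probe a chromosome (autosomes, with a configurable fraction
#' on chrX/chrY), a CpG-island flag and a gene accession, and designates
#' which autosomal probes will be truly hyper- or hypomethylated in tumors.
#' Hyper-designated probes fall in CGI with probability 0.9 and
#' hypo-designated ones with probability 0.27, reproducing the canonical
#' concentration of tumor hypermethylation inside islands; the CGI
#' probability of the remaining probes is solved so the marginal CGI
#' fraction equals `cfg$cgi_fraction` in expectation.
#'
#' @param cfg A [cohort_config].
#' @return A tibble with columns `probe_id`, `chromosome`, `cgi`, `gene`,
#'   `designation` (`"hyper"`, `"hypo"` or `"none"`; generator ground-truth
#'   plumbing, ignored by the analysis stages).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_probes
  with_seed(derive_seed(cfg$seed, 1L), {
    probe_id <- sprintf("cg%07d", seq_len(n))
    n_sex <- round(cfg$sex_chr_fraction * n)
    sex_idx <- if (n_sex > 0) sample.int(n, n_sex) else integer(0)
    chromosome <- sample(paste0("chr", 1:22), n, replace = TRUE)
    if (n_sex > 0) {
      chromosome[sex_idx] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE,
                                    prob = c(0.8, 0.2))
    }
    autosomal <- setdiff(seq_len(n), sex_idx)

    n_diff <- round(cfg$frac_diff_probes * n)
    n_diff <- min(n_diff, length(autosomal))
    diff_idx <- if (n_diff > 0) sample(autosomal, n_diff) else integer(0)
    n_hyper <- round(cfg$hyper_fraction * n_diff)
    designation <- rep("none", n)
    designation[diff_idx[seq_len(n_hyper)]] <- "hyper"
    designation[diff_idx[setdiff(seq_len(n_diff), seq_len(n_hyper))]] <- "hypo"

    p_hyper <- 0.9
    p_hypo <- 0.27
    f_hyper <- sum(designation == "hyper") / n
    f_hypo <- sum(designation == "hypo") / n
    f_rest <- 1 - f_hyper - f_hypo
    if (cfg$cgi_fraction %in% c(0, 1)) {
      p_cgi <- rep(cfg$cgi_fraction, n)
    } else {
      p_rest <- if (f_rest > 0) {
        (cfg$cgi_fraction - f_hyper * p_hyper - f_hypo * p_hypo) / f_rest
      } else {
        cfg$cgi_fraction
      }
      if (p_rest < 0 || p_rest > 1) {
        warn("CGI bias of designated probes incompatible with `cgi_fraction`; clamping.")
        p_rest <- min(max(p_rest, 0), 1)
      }
      p_cgi <- ifelse(designation == "hyper", p_hyper,
                      ifelse(designation == "hypo", p_hypo, p_rest))
    }
    cgi <- stats::runif(n) < p_cgi

    # ~2 probes per gene on average, as on promoter-centric 27K-style arrays
    n_genes <- max(1L, ceiling(n / 1.9))
    gene <- sprintf("NM_%06d", sample.int(n_genes, n, replace = TRUE))

    tibble(probe_id = probe_id, chromosome = chromosome, cgi = cgi,
           gene = gene, designation = designation)
  })
}

#' Generate paired tumor/adjacent methylation data
#'
#' Beta-values follow a bimodal mixture (unmethylated mode ~ Beta(2,10),
#' methylated mode ~ Beta(10,2)); each probe has a latent baseline shared by
#' all adjacent tissues, tumor columns of truly differential probes are
#' shifted by the signed effect size, and subgroup-marker probes are
#' hypermethylated only in the subgroups that carry them: subgroup 2 carries
#' the full marker set while subgroups 1 and 3 carry disjoint halves, so
#' only subgroup 2 differs from normal tissue at every marker.
#'
#' @param cfg A [cohort_config].
#' @param ann Annotation from [generate_annotation()].
#' @return A list with elements `beta` (a [beta_matrix] with paired tumor and
#'   adjacent columns per patient), `detp` (matching detection-p matrix) and
#'   `truth` (ground-truth list: `subgroup`, `diff_probes`, `marker_probes`,
#'   `baseline`).
#' @export
generate_methylation <- function(cfg, ann) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (nrow(ann) != cfg$n_probes) abort("`ann` does not match `cfg`.")
  n <- cfg$n_probes
  npat <- cfg$n_patients
  with_seed(derive_seed(cfg$seed, 2L), {
    patients <- sprintf("P%03d", seq_len(npat))
    subgroup <- sample(rep.int(1:3, cfg$subgroup_sizes))
    names(subgroup) <- patients

    designation <- ann$designation
    baseline <- numeric(n)
    hyper <- designation == "hyper"
    hypo <- designation == "hypo"
    none <- designation == "none"
    baseline[hyper] <- stats::rbeta(sum(hyper), 2, 10)
    baseline[hypo] <- stats::rbeta(sum(hypo), 10, 2)
    # unmethylated mode dominates inside islands
    meth_mode <- stats::runif(n) < ifelse(ann$cgi, 0.2, 0.5)
    baseline[none & meth_mode] <- stats::rbeta(sum(none & meth_mode), 10, 2)
    baseline[none & !meth_mode] <- stats::rbeta(sum(none & !meth_mode), 2, 10)
    baseline <- pmin(pmax(baseline, 0.01), 0.99)

    delta <- numeric(n)
    delta[hyper] <- cfg$delta_beta_effect
    delta[hypo] <- -cfg$delta_beta_effect
    tumor_mean_base <- pmin(pmax(baseline + delta, 0.01), 0.99)
    delta_true <- tumor_mean_base - baseline

    # subgroup markers: hyper shifts carried by designated subgroups only
    n_marker <- round(cfg$frac_subgroup_probes * n)
    eligible <- which(none & !(ann$chromosome %in% c("chrX", "chrY")))
    n_marker <- min(n_marker, length(eligible))
    marker_idx <- if (n_marker > 0) sample(eligible, n_marker) else integer(0)
    half <- floor(n_marker / 2)
    set_a <- marker_idx[seq_len(half)]
    set_b <- setdiff(marker_idx, set_a)
    carriers <- list(`1` = set_a, `2` = marker_idx, `3` = set_b)

    phi <- cfg$beta_precision
    tumor_ids <- paste0(patients, "T")
    adj_ids <- paste0(patients, "N")
    mean_mat <- matrix(baseline, nrow = n, ncol = 2 * npat)
    colnames(mean_mat) <- c(tumor_ids, adj_ids)
    for (p in seq_len(npat)) {
      m <- tumor_mean_base
      carried <- carriers[[as.character(subgroup[p])]]
      if (length(carried)) {
        m[carried] <- pmin(m[carried] + cfg$delta_beta_effect, 0.99)
      }
      mean_mat[, p] <- m
    }
    values <- matrix(stats::rbeta(length(mean_mat), mean_mat * phi,
                                  (1 - mean_mat) * phi),
                     nrow = n, dimnames = dimnames(mean_mat))
    values <- pmin(pmax(values, 0.001), 0.999)

    detp <- matrix(stats::runif(length(values), 0, 0.01),
                   nrow = n, dimnames = dimnames(values))
    fail <- stats::runif(length(values)) < cfg$detection_fail_rate
    detp[fail] <- stats::runif(sum(fail), 0.05000001, 1)
    rownames(values) <- rownames(detp) <- ann$probe_id

    meta <- tibble(
      sample = c(tumor_ids, adj_ids),
      patient = rep(patients, 2),
      role = rep(c("tumor", "adjacent"), each = npat)
    )
    diff_probes <- tibble(
      probe_id = ann$probe_id[hyper | hypo],
      delta = delta_true[hyper | hypo],
      direction = ifelse(delta_true[hyper | hypo] > 0, "hyper", "hypo")
    )
    marker_probes <- tibble(
      probe_id = ann$probe_id[marker_idx],
      set = ifelse(marker_idx %in% set_a, "A", "B")
    )
    list(
      beta = beta_matrix(values, meta),
      detp = detp,
      truth = list(subgroup = subgroup, diff_probes = diff_probes,
                   marker_probes = marker_probes,
                   baseline = stats::setNames(baseline, ann$probe_id))
    )
  })
}

#' Generate two-platform expression data linked to methylation
#'
#' Produces two log2-expression matrices over disjoint patient subsets
#' (default 20 and 39 patients, each with paired tumor/adjacent columns).
#' A subset of differentially methylated genes is "coupled": their
#' expression tracks the probe's beta-value with a negative (silencing) or
#' positive slope, so hypermethylated-and-silenced genes are down-shifted in
#' tumors and inversely correlated with methylation. The second platform
#' receives a per-gene additive offset (SD `batch_shift`) and residual
#' variance scaling (`batch_scale`).
#'
#' @param cfg A [cohort_config].
#' @param meth Output of [generate_methylation()].
#' @param ann Annotation from [generate_annotation()].
#' @param split Number of patients on the first platform (default 20).
#' @return A list with `platform_a`, `platform_b` (both [expr_matrix]) and
#'   `truth` (tibbles `coupled_genes` and `batch_effects`).
#' @export
generate_expression <- function(cfg, meth, ann, split = 20L) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (split >= cfg$n_patients || split < 1) {
    abort("`split` must leave patients on both platforms.",
          class = "methcluster_config_error")
  }
  beta <- meth$beta
  truth <- meth$truth
  with_seed(derive_seed(cfg$seed, 3L), {
    genes <- sort(unique(ann$gene))
    n_g <- length(genes)
    patients <- unique(beta$sample_meta$patient)

    # couple a fraction of differentially methylated genes to their probe
    diff_ann <- ann[ann$designation != "none", ]
    diff_ann <- diff_ann[!duplicated(diff_ann$gene), ]
    n_coupled <- round(cfg$expr_coupled_frac * nrow(diff_ann))
    coupled <- diff_ann[sample.int(nrow(diff_ann), n_coupled), ]
    sign_c <- ifelse(stats::runif(n_coupled) < cfg$expr_inverse_frac, -1, 1)
    coupled_genes <- tibble(
      gene = coupled$gene, probe_id = coupled$probe_id,
      slope = sign_c * cfg$expr_slope,
      meth_direction = coupled$designation
    )

    alpha <- stats::rnorm(n_g, 8, 1.5)
    names(alpha) <- genes

    # methylation-independent tumor effects on some uncoupled genes
    free <- setdiff(genes, coupled_genes$gene)
    n_de <- round(cfg$expr_de_frac * length(free))
    de_genes <- sample(free, n_de)
    de_effect <- stats::setNames(
      sample(c(-1, 1), n_de, TRUE) * stats::rnorm(n_de, 0.8, 0.1), de_genes)

    sample_ids <- beta$sample_meta$sample
    is_tumor <- beta$sample_meta$role == "tumor"
    expr <- matrix(0, nrow = n_g, ncol = length(sample_ids),
                   dimnames = list(genes, sample_ids))
    expr[] <- alpha
    if (n_de > 0) {
      expr[de_genes, is_tumor] <- expr[de_genes, is_tumor] + de_effect
    }
    if (n_coupled > 0) {
      bsub <- beta$values[coupled_genes$probe_id, , drop = FALSE]
      centered <- bsub - truth$baseline[coupled_genes$probe_id]
      expr[coupled_genes$gene, ] <- expr[coupled_genes$gene, ] +
        coupled_genes$slope * centered
    }

    batch1_pat <- patients[seq_len(split)]
    batch2_pat <- setdiff(patients, batch1_pat)
    in_b1 <- beta$sample_meta$patient %in% batch1_pat
    shift <- stats::rnorm(n_g, 0, cfg$batch_shift)
    scale <- if (cfg$batch_scale == 1) rep(1, n_g) else {
      stats::rlnorm(n_g, log(cfg$batch_scale), 0.05)
    }

    noise_sd <- 0.5
    e1 <- expr[, in_b1, drop = FALSE] +
      matrix(stats::rnorm(n_g * sum(in_b1), 0, noise_sd), nrow = n_g)
    e2 <- expr[, !in_b1, drop = FALSE] + shift +
      matrix(stats::rnorm(n_g * sum(!in_b1), 0, noise_sd), nrow = n_g) *
        scale
    meta1 <- beta$sample_meta[in_b1, ]
    meta1$platform <- "agilent_like"
    meta2 <- beta$sample_meta[!in_b1, ]
    meta2$platform <- "beadchip_like"

    rownames(e1) <- paste0("PA_", genes)
    rownames(e2) <- paste0("PB_", genes)
    map1 <- tibble(feature_id = rownames(e1), accession = genes)
    map2 <- tibble(feature_id = rownames(e2), accession = genes)

    list(
      platform_a = expr_matrix(e1, meta1, map1),
      platform_b = expr_matrix(e2, meta2, map2),
      truth = list(
        coupled_genes = coupled_genes,
        de_genes = tibble(gene = de_genes, logfc = unname(de_effect)),
        batch_effects = tibble(gene = genes, shift = shift, scale = scale)
      )
    )
  })
}

#' Generate survival records with subgroup-linked hazards
#'
#' Event times are exponential with hazard `baseline_hazard` for subgroups 1
#' and 3 and `baseline_hazard * hr_groupB` for subgroup 2. Administrative
#' censoring times are uniform on (0, u), with u solved so the expected
#' censored fraction equals `censor_rate`. Clinical covariates are drawn
#' from [clinical_marginals()] independently of subgroup.
#'
#' @param cfg A [cohort_config].
#' @param subgroup Named integer vector of per-patient subgroup labels.
#' @param endpoint `"OS"` or `"DFS"` (disease-free times use a 1.5-fold
#'   baseline hazard).
#' @return A tibble of survival records: `patient`, `endpoint`, `time`
#'   (months), `event`, `group`, plus clinical covariates.
#' @export
generate_survival <- function(cfg, subgroup, endpoint = c("OS", "DFS")) {
  stopifnot(inherits(cfg, "cohort_config"))
  endpoint <- match.arg(endpoint)
  if (cfg$hr_groupB <= 0) {
    abort("`hr_groupB` must be > 0.", class = "methcluster_config_error")
  }
  patients <- names(subgroup)
  lam0 <- cfg$baseline_hazard * if (endpoint == "DFS") 1.5 else 1
  lam <- ifelse(subgroup == 2, lam0 * cfg$hr_groupB, lam0)
  with_seed(derive_seed(cfg$seed, if (endpoint == "OS") 4L else 5L), {
    t_event <- stats::rexp(length(lam), rate = lam)
    if (cfg$censor_rate == 0) {
      time <- t_event
      event <- rep(TRUE, length(lam))
    } else {
      cens_frac <- function(u) {
        mean((1 - exp(-lam * u)) / (lam * u))
      }
      u <- stats::uniroot(function(u) cens_frac(u) - cfg$censor_rate,
                          lower = 1e-6, upper = 1e6, tol = 1e-8)$root
      c_time <- stats::runif(length(lam), 0, u)
      time <- pmin(t_event, c_time)
      event <- t_event <= c_time
    }
    time <- pmax(time, 0.01)

    marg <- clinical_marginals()
    covs <- marg |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(draw = list(sample(.data$level, length(patients),
                                          replace = TRUE,
                                          prob = .data$n / sum(.data$n))),
                       .groups = "drop")
    cov_tbl <- stats::setNames(covs$draw, covs$parameter) |> as_tibble()

    dplyr::bind_cols(
      tibble(patient = patients, endpoint = endpoint,
             time = time, event = event, group = unname(subgroup)),
      cov_tbl
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs annotation, methylation, expression and survival generation with
#' substreams derived from `cfg$seed`, returning all matrices plus the
#' ground truth needed for recovery tests.
#'
#' @param cfg A [cohort_config].
#' @return A list with `config`, `annotation`, `beta`, `detp`,
#'   `expr` (list `platform_a`/`platform_b`), `survival` (OS and DFS rows)
#'   and `truth`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  # first-platform size mirrors the 20/39 split; scaled for small cohorts
  split <- if (cfg$n_patients >= 40) 20L else max(2L, cfg$n_patients %/% 3)
  expr <- generate_expression(cfg, meth, ann, split = split)
  surv <- dplyr::bind_rows(
    generate_survival(cfg, meth$truth$subgroup, "OS"),
    generate_survival(cfg, meth$truth$subgroup, "DFS")
  )
  truth <- c(meth$truth, expr$truth,
             list(log_hr_groupB = log(cfg$hr_groupB)))
  list(config = cfg, annotation = ann, beta = meth$beta, detp = meth$detp,
       expr = list(platform_a = expr$platform_a,
                   platform_b = expr$platform_b),
       survival = surv, truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the beta and detection-p matrices as TSV, the annotation as TSV,
#' per-platform expression TSVs with metadata CSVs, the clinical/survival
#' CSV and the ground truth as JSON; all round-trip through the package
#' readers.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_beta_matrix(cohort$beta, fp("beta.tsv"), fp("samples.csv"))
  write_matrix_tsv(cohort$detp, fp("detection_p.tsv"))
  readr::write_tsv(cohort$annotation, fp("annotation.tsv"))
  write_expr_matrix(cohort$expr$platform_a, fp("expr_platform_a.tsv"),
                    fp("expr_platform_a_samples.csv"),
                    fp("expr_platform_a_map.tsv"))
  write_expr_matrix(cohort$expr$platform_b, fp("expr_platform_b.tsv"),
                    fp("expr_platform_b_samples.csv"),
                    fp("expr_platform_b_map.tsv"))
  readr::write_csv(cohort$survival, fp("survival.csv"))
  truth <- cohort$truth
  truth$subgroup <- as.list(truth$subgroup)
  jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
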