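#' Configuration for the synthetic HCC-style cohort generator
#'
#' Collects every knob of the generator with defaults chosen to mirror the
#' structure of a paired tumor/adjacent 27K-style methylation study of 59
#' patients with three latent tumor subgroups, two-batch expression
#' profiling, and subgroup-linked survival.
#'
#' @param n_patients Number of patients; each contributes a tumor and an
#'   adjacent non-tumorous sample.
#' @param n_probes Number of CpG probes on the simulated array.
#' @param subgroup_sizes Integer vector summing to `n_patients`; sizes of the
#'   latent tumor subgroups 1..3.
#' @param frac_diff_probes Fraction of probes truly differential between
#'   tumor and adjacent tissue.
#' @param hyper_fraction Of the truly differential probes, the fraction
#'   hypermethylated in tumors (the rest are hypomethylated).
#' @param delta_beta_effect Mean absolute beta-shift of true differential
#'   probes.
#' @param frac_subgroup_probes Fraction of probes carrying subgroup-specific
#'   hypermethylation (the clustering markers).
#' @param cgi_fraction Marginal fraction of probes annotated as CpG-island.
#' @param sex_chr_fraction Fraction of probes placed on chrX/chrY.
#' @param batch_shift SD of the per-gene additive platform offset applied to
#'   the second expression batch (log2 units).
#' @param batch_scale Multiplicative dispersion factor of the second batch's
#'   residual noise.
#' @param hr_groupB True hazard ratio of subgroup 2 versus the others.
#' @param censor_rate Target fraction of administratively censored patients.
#' @param beta_precision Beta-distribution precision (a+b) of per-sample
#'   methylation noise around each probe's latent mean.
#' @param detection_fail_rate Per-cell probability of a failed detection
#'   (detection p drawn above 0.05).
#' @param baseline_hazard Event hazard per month for subgroups 1 and 3.
#' @param expr_coupled_frac Fraction of differentially methylated genes whose
#'   expression is driven by their probe's beta-value.
#' @param expr_inverse_frac Of the coupled genes, the fraction with inverse
#'   (negative) methylation-expression coupling.
#' @param expr_slope Absolute log2-expression change per unit beta-change for
#'   coupled genes.
#' @param expr_de_frac Fraction of non-coupled genes given a
#'   methylation-independent tumor expression effect.
#' @param seed Integer seed driving all generator randomness; per-operation
#'   substreams are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 59L,
                          n_probes = 5000L,
                          subgroup_sizes = c(20L, 19L, 20L),
                          frac_diff_probes = 0.16,
                          hyper_fraction = 0.46,
                          delta_beta_effect = 0.25,
                          frac_subgroup_probes = 0.04,
                          cgi_fraction = 0.7,
                          sex_chr_fraction = 0.03,
                          batch_shift = 0.8,
                          batch_scale = 1.5,
                          hr_groupB = 4.0,
                          censor_rate = 0.6,
                          beta_precision = 50,
                          detection_fail_rate = 0.005,
                          baseline_hazard = log(2) / 36,
                          expr_coupled_frac = 0.4,
                          expr_inverse_frac = 0.44,
                          expr_slope = 3,
                          expr_de_frac = 0.1,
                          seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 3L)
  n_probes <- check_count(n_probes, "n_probes", min = 10L)
  if (length(subgroup_sizes) != 3L || any(subgroup_sizes < 1)) {
    abort("`subgroup_sizes` must be three positive counts.",
          class = "methcluster_config_error")
  }
  if (sum(subgroup_sizes) != n_patients) {
    abort("`subgroup_sizes` must sum to `n_patients`.",
          class = "methcluster_config_error")
  }
  for (f in c("frac_diff_probes", "hyper_fraction", "delta_beta_effect",
              "frac_subgroup_probes", "cgi_fraction", "sex_chr_fraction",
              "censor_rate", "detection_fail_rate", "expr_coupled_frac",
              "expr_inverse_frac", "expr_de_frac")) {
    check_fraction(get(f), f)
  }
  if (!is.numeric(hr_groupB) || hr_groupB <= 0) {
    abort("`hr_groupB` must be > 0.", class = "methcluster_config_error")
  }
  if (batch_scale <= 0 || batch_shift < 0) {
    abort("`batch_shift` must be >= 0 and `batch_scale` > 0.",
          class = "methcluster_config_error")
  }
  structure(list(
    n_patients = n_patients, n_probes = n_probes,
    subgroup_sizes = as.integer(subgroup_sizes),
    frac_diff_probes = frac_diff_probes, hyper_fraction = hyper_fraction,
    delta_beta_effect = delta_beta_effect,
    frac_subgroup_probes = frac_subgroup_probes,
    cgi_fraction = cgi_fraction, sex_chr_fraction = sex_chr_fraction,
    batch_shift = batch_shift, batch_scale = batch_scale,
    hr_groupB = hr_groupB, censor_rate = censor_rate,
    beta_precision = beta_precision,
    detection_fail_rate = detection_fail_rate,
    baseline_hazard = baseline_hazard,
    expr_coupled_frac = expr_coupled_frac,
    expr_inverse_frac = expr_inverse_frac,
    expr_slope = expr_slope, expr_de_frac = expr_de_frac,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d patients (subgroups %s), %d probes, ",
                     "diff %.0f%%, markers %.0f%%, HR(B) %.1f, seed %d\n"),
              x$n_patients, paste(x$subgroup_sizes, collapse = "/"),
              x$n_probes, 100 * x$frac_diff_probes,
              100 * x$frac_subgroup_probes, x$hr_groupB, x$seed))
  invisible(x)
}

#' Marginal clinicopathological frequencies of the simulated cohort
#'
#' The per-variable counts used by [generate_survival()] to draw clinical
#' covariates (independently of subgroup), together with the rounded
#' percentages each count implies. Totals below 59 reflect variables with
#' missing records in the cohort the frequencies describe.
#'
#' @return A tibble with columns `parameter`, `level`, `n`, `total`, `pct`.
#' @export
clinical_marginals <- function() {
  tibble::tribble(
    ~parameter,        ~level,        ~n, ~total, ~pct,
    "age_ge65",        "yes",         31L, 59L, 53,
    "age_ge65",        "no",          28L, 59L, 47,
    "gender",          "male",        53L, 59L, 90,
    "gender",          "female",       6L, 59L, 10,
    "hbv",             "positive",    36L, 59L, 61,
    "hbv",             "negative",    23L, 59L, 39,
    "tumor_size_ge5",  "yes",         33L, 59L, 56,
    "tumor_size_ge5",  "no",          26L, 59L, 44,
    "differentiation", "I",            5L, 59L, 8.5,
    "differentiation", "II",          23L, 59L, 39,
    "differentiation", "III",         26L, 59L, 44,
    "differentiation", "IV",           5L, 59L, 8.5,
    "tnm",             "1",           32L, 58L, 55,
    "tnm",             "2",           16L, 58L, 28,
    "tnm",             "3",           10L, 58L, 17,
    "cirrhosis",       "absent",      37L, 58L, 64,
    "cirrhosis",       "present",     21L, 58L, 36,
    "multifocality",   "absent",      45L, 55L, 82,
    "multifocality",   "present",     10L, 55L, 18,
    "encapsulation",   "absent",      35L, 53L, 66,
    "encapsulation",   "present",     18L, 53L, 34,
    "afp_ge100",       "yes",         36L, 51L, 71,
    "afp_ge100",       "no",          15L, 51L, 29
  )
}
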