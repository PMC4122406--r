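#' Kaplan-Meier product-limit estimate
#'
#' @param records Data frame with columns `time` (> 0) and `event`
#'   (logical/0-1); optional `group` for stratified curves.
#' @return A tibble with one row per distinct time: `group` (if supplied),
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) < 1) abort("Need at least one record.")
  if (any(records$time <= 0)) abort("Times must be positive.")
  has_group <- "group" %in% names(records)
  fml <- if (has_group) {
    survival::Surv(time, event) ~ group
  } else {
    survival::Surv(time, event) ~ 1
  }
  fit <- survival::survfit(fml, data = records)
  s <- summary(fit, censored = TRUE)
  tibble(
    group = if (has_group) {
      sub("^group=", "", as.character(s$strata))
    } else {
      "all"
    },
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, surv = s$surv
  )
}

#' Generalized (Gehan-Breslow) Wilcoxon test
#'
#' Weighted two-group log-rank test with weight equal to the total number
#' at risk at each event time, emphasizing early survival differences:
#' `U = sum w_i (d_1i - n_1i d_i / n_i)` with the hypergeometric variance
#' `V = sum w_i^2 d_i (n_1i/n_i)(1 - n_1i/n_i)(n_i - d_i)/(n_i - 1)`, and
#' `chi2 = U^2 / V` on 1 df. `weight = "logrank"` sets `w_i = 1`,
#' recovering the standard log-rank test.
#'
#' @param records Data frame with `time`, `event`, `group` (two groups).
#' @param weight `"gehan"` (w = n at risk) or `"logrank"` (w = 1).
#' @return A one-row tibble: `chi2`, `df`, `p`, `observed_1`, `expected_1`.
#' @export
gehan_wilcoxon <- function(records, weight = c("gehan", "logrank")) {
  weight <- match.arg(weight)
  groups <- factor(records$group)
  if (nlevels(groups) != 2) abort("Exactly two groups are required.")
  if (any(table(groups) == 0)) abort("A group is empty.")
  if (sum(records$event) < 1) abort("At least one event is required.")
  g1 <- groups == levels(groups)[1]
  times <- sort(unique(records$time[records$event == 1]))
  U <- 0; V <- 0; O1 <- 0; E1 <- 0
  for (t in times) {
    at_risk <- records$time >= t
    n_i <- sum(at_risk)
    n_1i <- sum(at_risk & g1)
    d_i <- sum(records$time == t & records$event == 1)
    d_1i <- sum(records$time == t & records$event == 1 & g1)
    w <- if (weight == "gehan") n_i else 1
    e_1i <- n_1i * d_i / n_i
    U <- U + w * (d_1i - e_1i)
    if (n_i > 1) {
      V <- V + w^2 * d_i * (n_1i / n_i) * (1 - n_1i / n_i) *
        (n_i - d_i) / (n_i - 1)
    }
    O1 <- O1 + d_1i
    E1 <- E1 + e_1i
  }
  chi2 <- if (V > 0) U^2 / V else 0
  tibble(chi2 = chi2, df = 1L,
         p = stats::pchisq(chi2, 1, lower.tail = FALSE),
         observed_1 = O1, expected_1 = E1)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling, Wald standard error
#' and a 95% confidence interval on the hazard-ratio scale. The first
#' factor level is the reference. Non-convergence or monotone likelihood
#' (complete separation) is flagged rather than silently reported.
#'
#' @param records Data frame with `time`, `event` and the covariate column.
#' @param covariate Name of a binary/factor or numeric covariate column.
#' @return A `cox_fit`: one-row tibble with `term`, `estimate` (log HR),
#'   `std_error`, `hr`, `conf_low`, `conf_high`, `p`, `flagged`.
#' @export
cox_univariate <- function(records, covariate) {
  if (!covariate %in% names(records)) {
    abort(sprintf("Column '%s' not found.", covariate))
  }
  if (sum(records$event) < 1) abort("At least one event is required.")
  x <- records[[covariate]]
  if (is.character(x)) x <- factor(x)
  d <- data.frame(time = records$time, event = as.integer(records$event),
                  x = x)
  if (length(unique(stats::na.omit(x))) < 2) {
    return(structure(tibble(term = covariate, estimate = 0, std_error = NA_real_,
                            hr = 1, conf_low = NA_real_, conf_high = NA_real_,
                            p = NA_real_, flagged = FALSE),
                     class = c("cox_fit", class(tibble()))))
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = d,
                    ties = "breslow",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(stats::vcov(fit)))[1]
  flagged <- warned || !is.finite(b) || abs(b) > 15 || !is.finite(se)
  out <- tibble(
    term = covariate, estimate = b, std_error = unname(se),
    hr = exp(b), conf_low = exp(b - 1.96 * se),
    conf_high = exp(b + 1.96 * se),
    p = 2 * stats::pnorm(-abs(b / se)),
    flagged = flagged
  )
  class(out) <- c("cox_fit", class(out))
  out
}

#' @export
tidy.cox_fit <- function(x, ...) as_tibble(x)

#' @export
glance.cox_fit <- function(x, ...) {
  tibble(hr = x$hr, conf_low = x$conf_low, conf_high = x$conf_high,
         p = x$p, flagged = x$flagged)
}

#' Merge subgroups into a binary grouping
#'
#' Relabels subgroup labels according to a named specification, e.g.
#' merging subgroups 1 and 3 into "A" and renaming subgroup 2 to "B".
#'
#' @param labels Vector of observed labels.
#' @param merge_spec Named list mapping new labels to vectors of old
#'   labels; must cover every observed label exactly once.
#' @return Character vector of new labels.
#' @export
merge_groups <- function(labels,
                         merge_spec = list(A = c(1, 3), B = 2)) {
  old <- unlist(merge_spec)
  if (anyDuplicated(old)) abort("`merge_spec` assigns a label twice.")
  unmapped <- setdiff(unique(labels), old)
  if (length(unmapped)) {
    abort(paste0("Labels not covered by `merge_spec`: ",
                 paste(unmapped, collapse = ", ")))
  }
  new <- rep(names(merge_spec), lengths(merge_spec))
  out <- new[match(labels, old)]
  names(out) <- names(labels)
  out
}

#' Association between subgroups and clinical variables
#'
#' Fisher's exact test of each categorical clinical variable against the
#' subgroup labels. Tables up to 3x4 are evaluated exactly; larger tables
#' fall back to a Monte-Carlo estimate whose simulation size is reported.
#'
#' @param labels Subgroup label per patient.
#' @param clinical_table Data frame of categorical covariates (one row per
#'   patient, aligned with `labels`).
#' @param b Monte-Carlo replicates for large tables.
#' @return A tibble with `variable`, `p`, `method`, `mc_se` (NA for exact).
#' @export
fisher_association <- function(labels, clinical_table, b = 10000L) {
  purrr::imap_dfr(clinical_table, function(v, nm) {
    v <- factor(v)
    if (nlevels(droplevels(v)) < 2) {
      warn(sprintf("Variable '%s' has a single level; p is NA.", nm))
      return(tibble(variable = nm, p = NA_real_, method = "none",
                    mc_se = NA_real_))
    }
    tab <- table(labels, v)
    exact_ok <- nrow(tab) <= 3 && ncol(tab) <= 4
    ft <- if (exact_ok) {
      stats::fisher.test(tab, workspace = 2e7)
    } else {
      stats::fisher.test(tab, simulate.p.value = TRUE, B = b)
    }
    tibble(variable = nm, p = ft$p.value,
           method = if (exact_ok) "exact" else "monte-carlo",
           mc_se = if (exact_ok) NA_real_ else sqrt(ft$p.value *
                                                      (1 - ft$p.value) / b))
  })
}
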