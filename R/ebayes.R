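#' Row-wise two-group ANOVA / t-test
#'
#' Vectorized per-feature comparison of two groups. Unpaired mode is the
#' one-way ANOVA F on the group factor (identical to the squared
#' pooled-variance t, with p from F(1, n-2)); paired mode is the paired t
#' on within-patient differences. The effect is mean(group 2) minus
#' mean(group 1), where group levels are taken in factor order.
#'
#' @param values Numeric feature-by-sample matrix (`NA` allowed; pairwise
#'   complete values are used per feature).
#' @param groups Vector of two group labels, one per column.
#' @param paired If `TRUE`, `pair_id` must identify the pairing and
#'   within-pair differences are tested.
#' @param pair_id Pairing identifier per column (e.g. patient id).
#' @return A tibble with columns `feature`, `effect`, `statistic` (t), `df`,
#'   `p`, `q` (Benjamini-Hochberg adjusted).
#' @export
two_group_anova <- function(values, groups, paired = FALSE, pair_id = NULL) {
  values <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) abort("`groups` must have exactly two levels.")
  g2 <- groups == levels(groups)[2]
  if (sum(g2) < 2 || sum(!g2) < 2) abort("Need >= 2 samples per group.")

  if (paired) {
    if (is.null(pair_id)) abort("Paired mode needs `pair_id`.")
    ids1 <- pair_id[!g2]
    ids2 <- pair_id[g2]
    if (!setequal(ids1, ids2) || anyDuplicated(ids1) || anyDuplicated(ids2)) {
      abort("Paired mode needs a complete one-to-one pairing.")
    }
    d <- values[, g2, drop = FALSE][, match(ids1, ids2), drop = FALSE] -
      values[, !g2, drop = FALSE]
    n <- rowSums(!is.na(d))
    eff <- rowMeans(d, na.rm = TRUE)
    s2 <- row_vars(d, na.rm = TRUE)
    df <- n - 1
    se <- sqrt(s2 / n)
    stat <- eff / se
  } else {
    x1 <- values[, !g2, drop = FALSE]
    x2 <- values[, g2, drop = FALSE]
    n1 <- rowSums(!is.na(x1))
    n2 <- rowSums(!is.na(x2))
    m1 <- rowMeans(x1, na.rm = TRUE)
    m2 <- rowMeans(x2, na.rm = TRUE)
    v1 <- row_vars(x1, na.rm = TRUE)
    v2 <- row_vars(x2, na.rm = TRUE)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    eff <- m2 - m1
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    stat <- eff / se
  }
  p <- 2 * stats::pt(-abs(stat), df)
  # degenerate: no variance and no effect -> uninformative by convention
  degenerate <- !is.finite(stat)
  p[degenerate & eff == 0] <- 1
  stat[degenerate & eff == 0] <- 0
  tibble(feature = rownames(values) %||% as.character(seq_len(nrow(values))),
         effect = unname(eff), statistic = unname(stat), df = unname(df),
         p = unname(p), q = bh_adjust(unname(p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled inverse-chi-squared prior to per-feature
#' residual variances, by matching the mean and spread of
#' `log(s_g^2)` through digamma/trigamma identities. When the observed
#' spread does not exceed what the residual degrees of freedom alone imply,
#' the prior degrees of freedom are infinite (complete shrinkage).
#'
#' @param s_g_sq Per-feature residual variances.
#' @param d_g Residual degrees of freedom (scalar or per-feature).
#' @return A list with `d0` (prior df, possibly `Inf`) and `s0_sq` (prior
#'   variance).
#' @export
fit_variance_prior <- function(s_g_sq, d_g) {
  ok <- is.finite(s_g_sq) & s_g_sq > 0 & d_g > 0
  if (sum(ok) < 10) abort("Need >= 10 positive variances to fit the prior.")
  if (all(s_g_sq[ok] == 0)) abort("All variances are zero.")
  s2 <- s_g_sq[ok]
  dg <- rep_len(d_g, length(s_g_sq))[ok]
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  n <- length(e)
  evar <- sum((e - mean(e))^2) / (n - 1) - mean(trigamma(dg / 2))
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Too few features to estimate a prior: fall back to no moderation
# (ordinary t), which is the d0 = 0 limit.
fit_prior_or_fallback <- function(s_g_sq, d_g) {
  ok <- is.finite(s_g_sq) & s_g_sq > 0 & d_g > 0
  if (sum(ok) < 10) {
    return(list(d0 = 0, s0_sq = mean(s_g_sq[ok])))
  }
  fit_variance_prior(s_g_sq, d_g)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (as convex in y).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Posterior (moderated) variances
#'
#' Shrinks per-feature variances toward the fitted prior:
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`.
#'
#' @param s_g_sq Per-feature residual variances.
#' @param d_g Residual degrees of freedom.
#' @param prior Output of [fit_variance_prior()].
#' @return Numeric vector of posterior variances.
#' @export
posterior_variance <- function(s_g_sq, d_g, prior) {
  if (is.infinite(prior$d0)) return(rep_len(prior$s0_sq, length(s_g_sq)))
  (prior$d0 * prior$s0_sq + d_g * s_g_sq) / (prior$d0 + d_g)
}

#' Moderated t-statistics
#'
#' Empirical-Bayes t-test: effects divided by posterior standard errors,
#' referred to a t distribution with `d0 + d_g` degrees of freedom (normal
#' when the prior df are infinite). With `d0 = 0` this reduces exactly to
#' the ordinary t-test.
#'
#' @param values Feature-by-sample matrix.
#' @param groups Two-level group labels per column.
#' @param prior Optional pre-fitted prior; fitted from the data if `NULL`.
#' @return A tibble with `feature`, `effect`, `s2_post`, `statistic`, `df`,
#'   `p`, `q`, plus the fitted `d0`/`s0_sq` as attributes.
#' @export
moderated_t <- function(values, groups, prior = NULL) {
  values <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) abort("`groups` must have exactly two levels.")
  g2 <- groups == levels(groups)[2]
  n1 <- rowSums(!is.na(values[, !g2, drop = FALSE]))
  n2 <- rowSums(!is.na(values[, g2, drop = FALSE]))
  m1 <- rowMeans(values[, !g2, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(values[, g2, drop = FALSE], na.rm = TRUE)
  v1 <- row_vars(values[, !g2, drop = FALSE], na.rm = TRUE)
  v2 <- row_vars(values[, g2, drop = FALSE], na.rm = TRUE)
  d_g <- n1 + n2 - 2
  s_g_sq <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d_g
  stderr_unit <- sqrt(1 / n1 + 1 / n2)
  eff <- m2 - m1
  if (is.null(prior)) prior <- fit_prior_or_fallback(s_g_sq, d_g)
  moderated_from_fit(eff, s_g_sq, d_g, stderr_unit, prior,
                     features = rownames(values))
}

#' @rdname moderated_t
#' @param effects Per-feature effect estimates.
#' @param s_g_sq Per-feature residual variances.
#' @param d_g Residual degrees of freedom.
#' @param stderr_unit Unit standard error multiplier (e.g.
#'   `sqrt(1/n1 + 1/n2)`); must be positive.
#' @param features Optional feature names.
#' @export
moderated_from_fit <- function(effects, s_g_sq, d_g, stderr_unit, prior,
                               features = NULL) {
  if (any(stderr_unit <= 0)) abort("`stderr_unit` must be positive.")
  s2_post <- posterior_variance(s_g_sq, d_g, prior)
  stat <- effects / (sqrt(s2_post) * stderr_unit)
  df_total <- prior$d0 + d_g
  p <- if (is.infinite(prior$d0)) {
    2 * stats::pnorm(-abs(stat))
  } else {
    2 * stats::pt(-abs(stat), df_total)
  }
  out <- tibble(
    feature = features %||% as.character(seq_along(effects)),
    effect = unname(effects), s2_post = unname(s2_post),
    statistic = unname(stat), df = unname(rep_len(df_total, length(stat))),
    p = unname(p), q = bh_adjust(unname(p))
  )
  attr(out, "prior") <- prior
  out
}

#' Moderated F across k groups
#'
#' Between-group mean square divided by the posterior variance, with
#' `(k - 1, d0 + d_g)` degrees of freedom. Used for subgroup-discriminating
#' feature selection.
#'
#' @param values Feature-by-sample matrix.
#' @param groups Group labels (>= 2 levels) per column.
#' @param prior Optional pre-fitted prior.
#' @return A tibble with `feature`, `ms_between`, `s2_post`, `statistic`,
#'   `df1`, `df2`, `p`, `q`.
#' @export
moderated_f <- function(values, groups, prior = NULL) {
  values <- as.matrix(values)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) abort("Need >= 2 groups.")
  n <- ncol(values)
  counts <- table(groups)
  if (any(counts < 2)) abort("Need >= 2 samples per group.")
  grand <- rowMeans(values, na.rm = TRUE)
  ss_between <- 0
  ss_within <- 0
  for (lv in levels(groups)) {
    sub <- values[, groups == lv, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    ss_between <- ss_between + counts[[lv]] * (m - grand)^2
    ss_within <- ss_within + rowSums((sub - m)^2, na.rm = TRUE)
  }
  d_g <- n - k
  s_g_sq <- ss_within / d_g
  ms_between <- ss_between / (k - 1)
  if (is.null(prior)) prior <- fit_prior_or_fallback(s_g_sq, d_g)
  s2_post <- posterior_variance(s_g_sq, d_g, prior)
  stat <- ms_between / s2_post
  df2 <- prior$d0 + d_g
  p <- if (is.infinite(prior$d0)) {
    stats::pchisq((k - 1) * stat, df = k - 1, lower.tail = FALSE)
  } else {
    stats::pf(stat, k - 1, df2, lower.tail = FALSE)
  }
  out <- tibble(
    feature = rownames(values) %||% as.character(seq_len(nrow(values))),
    ms_between = unname(ms_between), s2_post = unname(s2_post),
    statistic = unname(stat), df1 = k - 1,
    df2 = unname(rep_len(df2, length(stat))), p = unname(p),
    q = bh_adjust(unname(p))
  )
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validated front on the stock
#' implementation.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}
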