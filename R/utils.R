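#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Fractions get validated in many constructors; one message format throughout.
check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "methcluster_config_error")
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in [%s, %s]; got %g.", name,
                  if (allow_zero) "0" else "0)", if (allow_one) "1" else "1)", x),
          class = "methcluster_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "methcluster_config_error")
  }
  invisible(as.integer(x))
}

# Derive independent-looking substreams from one user seed so that stage
# reruns reproduce a full-pipeline run. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 7919) %%
               2147483629)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Adjusted Rand index between two label vectors (chance-corrected agreement).
ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

row_vars <- function(x, na.rm = FALSE) {
  n <- if (na.rm) rowSums(!is.na(x)) else ncol(x)
  mu <- rowMeans(x, na.rm = na.rm)
  rowSums((x - mu)^2, na.rm = na.rm) / pmax(n - 1, 1)
}
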