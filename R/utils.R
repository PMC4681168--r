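# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Clip beta values into the open unit interval. The pipeline operates on
# methylation fractions; values are kept away from 0/1 so logit transforms
# stay finite.
clip_beta <- function(x, lo = 0.001, hi = 0.999) {
  pmin(pmax(x, lo), hi)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Validate a beta matrix: numeric, in [0, 1), unique dimnames.
check_beta_matrix <- function(beta) {
  assert_that(is.matrix(beta) && is.numeric(beta),
              "beta must be a numeric matrix (probes x samples)")
  assert_that(!is.null(rownames(beta)) && !is.null(colnames(beta)),
              "beta must carry probe rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(beta)), "duplicate probe IDs in beta")
  assert_that(!anyDuplicated(colnames(beta)), "duplicate sample IDs in beta")
  assert_that(all(is.finite(beta)) && min(beta) >= 0 && max(beta) < 1,
              "beta values must lie in [0, 1)")
  invisible(beta)
}

# Row-wise variance of a matrix without apply() overhead.
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

# Seed an RNG stream deterministically from a base seed and a stream index,
# staying below .Machine$integer.max.
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) * 1103L + stream * 7919L) %% 2147483629)
}
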