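# Reference-based leukocyte deconvolution by regression calibration:
# each sample's beta profile over discriminating probes is modeled as a
# nonnegative combination of purified-cell reference profiles.

# Lawson-Hanson active-set nonnegative least squares: min ||Ax - b||, x >= 0.
nnls_solve <- function(A, b, tol = 1e-10, max_iter = NULL) {
  p <- ncol(A)
  if (is.null(max_iter)) max_iter <- 10L * p
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- solve(crossprod(Ap), crossprod(Ap, b))
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Estimate leukocyte proportions from bulk methylation profiles
#'
#' For each sample, solves the constrained least-squares problem
#' `min || b - R w ||^2` subject to `w >= 0`, where `R` holds the reference
#' profiles of the purified cell types (CD8T, CD4T, Bcell, NK, Mono, Gran
#' by default) over the discriminating probes. No sum-to-one constraint is
#' imposed: the estimates are relative proportions and enter downstream
#' models as separate covariates.
#'
#' @param beta Beta matrix (probes x samples); must contain the reference's
#'   discriminating probes.
#' @param reference A `cell_reference` (see [generate_cell_reference()]) or
#'   a probes x cell-types matrix of reference profiles.
#' @param max_condition Maximum acceptable condition number of the
#'   reference matrix before refusing as rank-deficient.
#' @return A samples x cell-types matrix of nonnegative estimates, class
#'   `cell_proportions`.
#' @export
estimate_cell_proportions <- function(beta, reference,
                                      max_condition = 1e8) {
  if (inherits(reference, "cell_reference")) {
    probes <- intersect(reference$discriminating, rownames(beta))
    R <- reference$profiles[probes, , drop = FALSE]
  } else {
    probes <- intersect(rownames(reference), rownames(beta))
    R <- reference[probes, , drop = FALSE]
  }
  assert_that(length(probes) >= ncol(R),
              "need at least as many discriminating probes as cell types")
  kappa_R <- kappa(R, exact = TRUE)
  if (kappa_R > max_condition)
    stopf("reference matrix is rank-deficient (condition number %.3g)",
          kappa_R)
  B <- beta[probes, , drop = FALSE]
  est <- t(apply(B, 2L, function(b) nnls_solve(R, b)))
  dimnames(est) <- list(colnames(beta), colnames(R))
  class(est) <- c("cell_proportions", class(est))
  est
}

#' Append estimated cell proportions to a sample sheet
#'
#' @param sample_sheet Sample sheet `data.frame` with a `sample_id` column.
#' @param proportions Output of [estimate_cell_proportions()].
#' @return The sample sheet with one column per cell type.
#' @export
add_cell_proportions <- function(sample_sheet, proportions) {
  assert_that(all(sample_sheet$sample_id %in% rownames(proportions)),
              "proportions missing samples present in the sample sheet")
  cbind(sample_sheet,
        as.data.frame(unclass(proportions)[sample_sheet$sample_id, ,
                                           drop = FALSE]))
}
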