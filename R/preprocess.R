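#' Compute beta values from methylated/unmethylated intensities
#'
#' The methylation fraction at a CpG is `beta = M / (M + U + offset)`, with
#' the conventional offset of 100 intensity units stabilizing low-intensity
#' probes. Values are strictly below 1 for any nonnegative intensities and a
#' positive offset.
#'
#' @param M,U Nonnegative numeric matrices (probes x samples) of methylated
#'   and unmethylated fluorescent intensities, with matching dimensions.
#' @param offset Intensity offset added to the denominator (default 100).
#' @return A beta matrix with the dimnames of `M`.
#' @export
compute_beta <- function(M, U, offset = 100) {
  assert_that(identical(dim(M), dim(U)), "M and U must have the same shape")
  assert_that(all(M >= 0) && all(U >= 0), "negative intensities are invalid")
  assert_that(offset > 0, "offset must be positive")
  beta <- M / (M + U + offset)
  dimnames(beta) <- dimnames(M)
  beta
}

#' Filter 450K-style probes on quality and annotation criteria
#'
#' Removes the union of six probe classes:
#' 1. probes failing the detection p-value rule (see `detection_rule`);
#' 2. probes with bead count < 3 in at least 5% of samples;
#' 3. probes on sex chromosomes;
#' 4. non-CG probes;
#' 5. probes mapping ambiguously;
#' 6. probes with a SNP at the probed CG.
#'
#' The rules are conjunctive and order-independent. The wording "median
#' detection P value >= 0.01 in one or more samples" is ambiguous; the
#' default `"any"` reading removes a probe whose detection p is >= 0.01 in
#' at least one sample, `"median"` removes probes whose across-sample
#' median is >= 0.01.
#'
#' @param beta Beta matrix (probes x samples).
#' @param annot Probe annotation `data.frame` (see [generate_annotation()]).
#' @param qc List with matrices `detection_p` and `bead_count` aligned to
#'   `beta`.
#' @param detection_rule `"any"` (default) or `"median"`.
#' @param detection_p_threshold Detection p cutoff (default 0.01).
#' @param bead_min Minimum bead count (default 3).
#' @param bead_frac Sample fraction at which low bead counts fail a probe
#'   (default 0.05).
#' @return A list with `beta` (surviving probes) and `report`, a
#'   `filter_report` giving per-rule and total removal counts.
#' @export
filter_probes <- function(beta, annot, qc,
                          detection_rule = c("any", "median"),
                          detection_p_threshold = 0.01,
                          bead_min = 3L, bead_frac = 0.05) {
  detection_rule <- match.arg(detection_rule)
  probes <- rownames(beta)
  assert_that(all(probes %in% rownames(annot)),
              "annotation is missing probes present in beta")
  assert_that(identical(dim(qc$detection_p), dim(beta)) &&
                identical(dim(qc$bead_count), dim(beta)),
              "QC tables must match beta in shape")
  ann <- annot[probes, , drop = FALSE]

  fail_detect <- if (detection_rule == "any") {
    rowSums(qc$detection_p >= detection_p_threshold) >= 1L
  } else {
    apply(qc$detection_p, 1L, stats::median) >= detection_p_threshold
  }
  fail_bead <- rowMeans(qc$bead_count < bead_min) >= bead_frac
  fail_sex <- ann$chrom %in% c("chrX", "chrY", "X", "Y")
  fail_noncg <- as.logical(ann$is_noncg)
  fail_ambig <- as.logical(ann$is_ambiguous)
  fail_snp <- as.logical(ann$has_snp_at_cg)

  fail_any <- fail_detect | fail_bead | fail_sex | fail_noncg |
    fail_ambig | fail_snp
  keep <- !fail_any
  if (!any(keep)) stopf("no probes remain after filtering")

  report <- structure(list(
    n_input = length(probes),
    n_removed = sum(fail_any),
    n_surviving = sum(keep),
    removed_by_rule = c(detection_p = sum(fail_detect),
                        bead_count = sum(fail_bead),
                        sex_chromosome = sum(fail_sex),
                        non_cg = sum(fail_noncg),
                        ambiguous = sum(fail_ambig),
                        snp_at_cg = sum(fail_snp)),
    detection_rule = detection_rule,
    removed_probes = probes[fail_any]), class = "filter_report")
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Probe filter: %d of %d probes removed, %d surviving\n",
              x$n_removed, x$n_input, x$n_surviving))
  for (nm in names(x$removed_by_rule))
    cat(sprintf("  %-15s %6d\n", nm, x$removed_by_rule[[nm]]))
  invisible(x)
}

#' Empirical-Bayes batch adjustment of a beta matrix
#'
#' Location/scale batch-effect adjustment in the ComBat style: per probe,
#' the data are standardized against a least-squares fit retaining the
#' preserved covariates, per-batch location and scale parameters are
#' shrunk toward their across-probe moments with parametric empirical-Bayes
#' priors (normal prior on locations, inverse-gamma on scales), and the
#' adjusted values are back-transformed. Biological effects encoded in
#' `preserve` are retained.
#'
#' @param beta Beta matrix (probes x samples).
#' @param sample_sheet `data.frame` with a `batch_id` column and any
#'   covariates named in `preserve`; rows aligned with `colnames(beta)`.
#' @param preserve Character vector of `sample_sheet` columns to protect
#'   from adjustment (e.g. `"group"`). May be empty.
#' @param eb_iter,eb_tol Iterations/tolerance for the empirical-Bayes
#'   conditional-posterior fixed point.
#' @return A list with `beta` (adjusted matrix, clipped to (0, 1)) and
#'   `model`, a `batch_model` holding the shrunken per-batch location
#'   (`gamma_star`) and scale (`delta_star`) parameters and the prior
#'   hyperparameters.
#' @export
combat_adjust <- function(beta, sample_sheet, preserve = "group",
                          eb_iter = 100L, eb_tol = 1e-6) {
  assert_that(identical(colnames(beta), sample_sheet$sample_id),
              "sample_sheet rows must align with beta columns")
  batch <- factor(sample_sheet$batch_id)
  n_batch <- nlevels(batch)
  nb <- table(batch)
  if (any(nb < 2L))
    stopf("batch(es) with a single sample: %s",
          paste(names(nb)[nb < 2L], collapse = ", "))
  n <- ncol(beta)

  if (n_batch == 1L) {
    model <- structure(list(batches = levels(batch),
                            gamma_star = matrix(0, 1, nrow(beta)),
                            delta_star = matrix(1, 1, nrow(beta)),
                            hyper = NULL), class = "batch_model")
    return(list(beta = beta, model = model))
  }

  batch_design <- stats::model.matrix(~ 0 + batch)
  colnames(batch_design) <- levels(batch)
  mod <- NULL
  if (length(preserve)) {
    fml <- stats::as.formula(paste("~", paste(preserve, collapse = " + ")))
    mod <- stats::model.matrix(fml, data = sample_sheet)
    mod <- mod[, colnames(mod) != "(Intercept)", drop = FALSE]
  }
  X <- cbind(batch_design, mod)
  if (qr(X)$rank < ncol(X))
    stopf("design is rank-deficient: batch is confounded with a preserved covariate")

  dat <- beta  # probes x samples
  B_hat <- solve(crossprod(X), t(X) %*% t(dat))       # coef x probes
  grand_mean <- crossprod(nb / n, B_hat[seq_len(n_batch), , drop = FALSE])
  resid <- dat - t(X %*% B_hat)
  var_pooled <- rowSums(resid^2) / n

  stand_mean <- matrix(grand_mean, nrow(dat), n,
                       dimnames = dimnames(dat))
  if (!is.null(mod) && ncol(mod) > 0L) {
    stand_mean <- stand_mean +
      t(mod %*% B_hat[-seq_len(n_batch), , drop = FALSE])
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(0, n_batch, nrow(dat))
  delta_hat <- matrix(1, n_batch, nrow(dat))
  for (b in seq_len(n_batch)) {
    cols <- batch == levels(batch)[b]
    gamma_hat[b, ] <- rowMeans(s_data[, cols, drop = FALSE])
    delta_hat[b, ] <- row_vars(s_data[, cols, drop = FALSE])
  }

  # moment-matched hyperparameters (normal / inverse-gamma)
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1L, stats::var)
  a_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(n_batch)) {
    cols <- batch == levels(batch)[b]
    nbk <- sum(cols)
    g <- gamma_hat[b, ]; d <- delta_hat[b, ]
    g_new <- g; d_new <- pmax(d, 1e-12)
    sd_b <- s_data[, cols, drop = FALSE]
    for (it in seq_len(eb_iter)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (tau2[b] * nbk * g + d_new * gamma_bar[b]) /
        (tau2[b] * nbk + d_new)
      sse <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sse + b_prior[b]) / (nbk / 2 + a_prior[b] - 1)
      if (max(abs(g_new - g_old)) < eb_tol &&
          max(abs(d_new - d_old)) < eb_tol) break
    }
    gamma_star[b, ] <- g_new
    delta_star[b, ] <- d_new
  }

  adj <- s_data
  for (b in seq_len(n_batch)) {
    cols <- batch == levels(batch)[b]
    adj[, cols] <- (s_data[, cols, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta_star[b, ])
  }
  adj <- adj * sqrt(var_pooled) + stand_mean
  adj <- clip_beta(adj, lo = 1e-6, hi = 1 - 1e-6)

  model <- structure(list(batches = levels(batch),
                          gamma_star = gamma_star, delta_star = delta_star,
                          hyper = list(gamma_bar = gamma_bar, tau2 = tau2,
                                       a_prior = a_prior, b_prior = b_prior)),
                     class = "batch_model")
  list(beta = adj, model = model)
}

#' Classical multidimensional scaling of sample beta profiles
#'
#' Torgerson scaling of the pairwise Euclidean distances between sample
#' methylation profiles, used as a cohort QC view (e.g. to check whether
#' phenotype groups separate or batches cluster).
#'
#' @param beta Beta matrix (probes x samples).
#' @param n_dims Number of embedding dimensions (default 2).
#' @return A samples x `n_dims` coordinate matrix, centered at the origin.
#' @export
mds_embed <- function(beta, n_dims = 2L) {
  n <- ncol(beta)
  assert_that(n >= 3L, "MDS needs at least 3 samples")
  assert_that(n_dims < n, "n_dims must be smaller than the sample count")
  d <- stats::dist(t(beta))
  coords <- stats::cmdscale(d, k = n_dims)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  coords
}
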