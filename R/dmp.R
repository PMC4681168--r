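# Per-CpG differential methylation: covariate-adjusted linear models with
# empirical-Bayes variance moderation, Bonferroni correction and an
# effect-size (delta-beta) filter.

#' Build the per-sample design matrix for differential methylation
#'
#' Columns: intercept; group indicator (severe = 1, no/mild = 0); sex
#' (M = 1); age in years; and one column per estimated cell-type
#' proportion present in the sample sheet.
#'
#' @param sample_sheet Sample sheet with columns `group`, `sex`,
#'   `age_years`, and optionally cell-type columns.
#' @param celltypes Cell-type column names to include; defaults to
#'   whichever of CD8T, CD4T, Bcell, NK, Mono, Gran are present.
#' @return A numeric design matrix with an attribute `group_col` naming
#'   the group-effect column.
#' @export
build_design_matrix <- function(sample_sheet, celltypes = NULL) {
  if (is.null(celltypes))
    celltypes <- intersect(CELLTYPE_NAMES, colnames(sample_sheet))
  grp <- as.integer(sample_sheet$group == "severe")
  assert_that(all(sample_sheet$group %in% c("severe", "no_mild")),
              "group must be 'severe' or 'no_mild'")
  X <- cbind(intercept = 1,
             group_severe = grp,
             sex_male = as.integer(sample_sheet$sex == "M"),
             age_years = as.numeric(sample_sheet$age_years))
  if (length(celltypes))
    X <- cbind(X, as.matrix(sample_sheet[, celltypes, drop = FALSE]))
  rownames(X) <- sample_sheet$sample_id
  attr(X, "group_col") <- "group_severe"
  X
}

#' Fit per-probe ordinary least squares models
#'
#' Fits the same linear model to every probe at once via the normal
#' equations, returning the group-effect coefficient, the residual variance
#' and its degrees of freedom.
#'
#' @param beta Beta matrix (probes x samples).
#' @param design Design matrix from [build_design_matrix()] (samples x
#'   covariates), full column rank, aligned with `colnames(beta)`.
#' @return A list with `coef` (probes x covariates), `group_coef`,
#'   `s2` (residual variances), `df` (residual degrees of freedom),
#'   `v_group` (unscaled variance of the group coefficient), `design`.
#' @export
fit_probe_models <- function(beta, design) {
  n <- ncol(beta)
  p <- ncol(design)
  assert_that(n > p, "need more samples than covariates")
  qrX <- qr(design)
  if (qrX$rank < p) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):p]]
    stopf("design matrix is rank-deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  XtX_inv <- chol2inv(chol(crossprod(design)))
  coef <- beta %*% design %*% XtX_inv        # probes x covariates
  colnames(coef) <- colnames(design)
  resid <- beta - coef %*% t(design)
  df <- n - p
  s2 <- rowSums(resid^2) / df
  gcol <- attr(design, "group_col") %||% "group_severe"
  v_group <- XtX_inv[match(gcol, colnames(design)),
                     match(gcol, colnames(design))]
  list(coef = coef, group_coef = coef[, gcol], s2 = s2, df = df,
       v_group = v_group, design = design)
}

# Newton inversion of the trigamma function (solve trigamma(x) = y).
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok & y <= 0] <- Inf
  x <- 0.5 + 1 / y[ok]
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[ok]) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-12) break
  }
  out[ok] <- x
  out
}

#' Empirical-Bayes moderation of per-probe residual variances
#'
#' Models the per-probe sample variances as scaled chi-square draws around
#' a common prior variance `s0^2` with prior degrees of freedom `d0`,
#' estimating both by moment matching on the log scale (closed-form
#' trigamma inversion). The posterior variance for probe g is
#' `(d0 s0^2 + d s2_g) / (d0 + d)`; moderated t-statistics formed with it
#' have `d0 + d` degrees of freedom.
#'
#' @param s2 Per-probe residual variances (nonnegative).
#' @param df Residual degrees of freedom (single value, >= 1).
#' @param d0_override Force the prior df (e.g. 0 for no moderation,
#'   `Inf` for complete shrinkage); `NULL` estimates it.
#' @return A list with `d0`, `s0_2`, and `s2_post` (per-probe posterior
#'   variances).
#' @export
moderate_variances <- function(s2, df, d0_override = NULL) {
  df <- unique(as.numeric(df))
  assert_that(length(df) == 1L && df >= 1, "df must be a single value >= 1")
  assert_that(all(s2 >= 0), "variances must be nonnegative")
  m <- length(s2)
  # floor exact zeros (constant probes) before the log transform
  pos <- s2[s2 > 0]
  s2f <- if (length(pos)) pmax(s2, min(pos) * 1e-12) else pmax(s2, 1e-300)

  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_2 <- if (is.finite(d0) && d0 == 0) NA_real_ else exp(mean(log(s2f)))
  } else if (m < 10L) {
    warnf("fewer than 10 probes: skipping variance moderation (d0 = 0)")
    d0 <- 0
    s0_2 <- NA_real_
  } else {
    z <- log(s2f)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess dispersion beyond chi-square sampling: complete shrinkage
      d0 <- Inf
      s0_2 <- mean(s2f)
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, m)
             else if (d0 == 0) s2
             else (d0 * s0_2 + df * s2) / (d0 + df)
  names(s2_post) <- names(s2)
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Moderated t-statistics and p-values for the group effect
#'
#' @param fit Output of [fit_probe_models()].
#' @param moderation Output of [moderate_variances()]; computed from `fit`
#'   when `NULL`.
#' @return A list (class `moderated_stats`) with `t` (moderated
#'   t-statistics), `p` (two-sided), `p_bonferroni`, `df_total`, `d0`,
#'   `s0_2`, `s2_post`, and the group coefficients.
#' @export
moderated_t_stats <- function(fit, moderation = NULL) {
  if (is.null(moderation)) moderation <- moderate_variances(fit$s2, fit$df)
  se <- sqrt(moderation$s2_post * fit$v_group)
  t_mod <- fit$group_coef / se
  t_mod[se == 0] <- 0
  df_total <- moderation$d0 + fit$df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  m <- length(p)
  structure(list(t = t_mod, p = p, p_bonferroni = pmin(1, p * m),
                 df_total = df_total, d0 = moderation$d0,
                 s0_2 = moderation$s0_2, s2_post = moderation$s2_post,
                 group_coef = fit$group_coef), class = "moderated_stats")
}

#' Raw group mean beta difference (severe minus no/mild) per probe
#'
#' @param beta Beta matrix (probes x samples).
#' @param group Per-sample group labels (`"severe"` / `"no_mild"`).
#' @return Named numeric vector of delta-beta values.
#' @export
compute_delta_beta <- function(beta, group) {
  assert_that(ncol(beta) == length(group), "group labels must match samples")
  rowMeans(beta[, group == "severe", drop = FALSE]) -
    rowMeans(beta[, group != "severe", drop = FALSE])
}

#' Select differentially methylated positions
#'
#' Retains probes with Bonferroni-adjusted p below `alpha` and an absolute
#' raw group mean difference of at least `min_abs_delta` (default: the
#' conventional +/- 5% beta cutoff), sorted by raw p-value.
#'
#' @param stats A `moderated_stats` object (see [moderated_t_stats()]).
#' @param delta Per-probe delta-beta values aligned with `stats`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_abs_delta Minimum absolute delta-beta (default 0.05).
#' @param annotation Optional probe annotation to carry through.
#' @return A `data.frame` (class `dmp_result`) with columns `rank`,
#'   `probe_id`, `p`, `p_bonferroni`, `delta_beta`, `group_coef`, plus
#'   annotation columns when supplied. Zero rows is a valid result.
#' @export
select_dmps <- function(stats, delta, alpha = 0.05, min_abs_delta = 0.05,
                        annotation = NULL) {
  probe_ids <- names(stats$p) %||% names(delta)
  assert_that(length(stats$p) == length(delta),
              "stats and delta must be aligned")
  keep <- which(stats$p_bonferroni < alpha & abs(delta) >= min_abs_delta)
  keep <- keep[order(stats$p[keep])]
  res <- data.frame(rank = seq_along(keep),
                    probe_id = probe_ids[keep],
                    p = unname(stats$p[keep]),
                    p_bonferroni = unname(stats$p_bonferroni[keep]),
                    delta_beta = unname(delta[keep]),
                    group_coef = unname(stats$group_coef[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation) && nrow(res)) {
    ann_cols <- intersect(c("chrom", "pos", "gene", "feature", "cpg_context"),
                          colnames(annotation))
    res <- cbind(res, annotation[res$probe_id, ann_cols, drop = FALSE])
    rownames(res) <- NULL
  }
  class(res) <- c("dmp_result", class(res))
  res
}

#' One-call DMP analysis
#'
#' Builds the design (group + sex + age + cell proportions), fits per-probe
#' models, moderates variances, and selects DMPs.
#'
#' @param beta Beta matrix (probes x samples).
#' @param sample_sheet Sample sheet with covariates (cell-type columns
#'   included if they should enter the model).
#' @param alpha,min_abs_delta Selection thresholds, see [select_dmps()].
#' @param annotation Optional probe annotation carried into the result.
#' @param celltypes Passed to [build_design_matrix()].
#' @return A list with `dmps` (the `dmp_result`), `stats`
#'   (`moderated_stats` over all probes), and `delta_beta`.
#' @export
run_dmp_analysis <- function(beta, sample_sheet, alpha = 0.05,
                             min_abs_delta = 0.05, annotation = NULL,
                             celltypes = NULL) {
  design <- build_design_matrix(sample_sheet, celltypes)
  fit <- fit_probe_models(beta, design)
  stats <- moderated_t_stats(fit)
  delta <- compute_delta_beta(beta, sample_sheet$group)
  list(dmps = select_dmps(stats, delta, alpha, min_abs_delta, annotation),
       stats = stats, delta_beta = delta)
}
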