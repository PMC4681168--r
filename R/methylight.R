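# MethyLight quantification: standard-curve interpolation of qPCR Ct
# values, percent-methylated-reference (PMR) computation against a fully
# methylated (M.SssI) control, ROC-optimal thresholding and group tests.

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on `log(relative input quantity)` over a serial
#' dilution (default 4-fold). The amplification efficiency is recovered
#' from the slope as `exp(-1/slope)`; with perfect efficiency 2 and 4-fold
#' dilutions, consecutive standards are exactly 2 cycles apart.
#'
#' @param ct Ct values of the dilution series, most concentrated first.
#' @param dilution_factor Fold change between consecutive points.
#' @param min_points Minimum number of finite Ct points (default 3).
#' @param min_r2 Minimum fit R-squared before refusal (default 0.9).
#' @return A list of class `standard_curve` with `slope`, `intercept`
#'   (Ct at quantity 1), `efficiency`, `r2`, `n_points`.
#' @export
fit_standard_curve <- function(ct, dilution_factor = 4,
                               min_points = 3L, min_r2 = 0.9) {
  q <- dilution_factor^(-(seq_along(ct) - 1L))
  ok <- is.finite(ct)
  assert_that(sum(ok) >= min_points,
              "need at least %d finite dilution points", min_points)
  ct_ok <- ct[ok]
  # Ct must rise with dilution (most concentrated standard first)
  if (any(diff(ct_ok) < 0))
    stopf("dilution series is non-monotone")
  x <- log(q[ok])
  fit <- stats::lm.fit(cbind(1, x), ct_ok)
  slope <- fit$coefficients[2]
  assert_that(is.finite(slope) && slope < 0,
              "standard curve slope must be negative")
  r2 <- 1 - sum(fit$residuals^2) / sum((ct_ok - mean(ct_ok))^2)
  if (sum(ok) > 2L && r2 < min_r2)
    stopf("standard curve fit too poor (R^2 = %.3f < %.2f)", r2, min_r2)
  efficiency <- exp(-1 / slope)
  assert_that(efficiency > 1 && efficiency <= 2.2,
              "implied efficiency %.3f outside (1, 2.2]", efficiency)
  structure(list(slope = unname(slope),
                 intercept = unname(fit$coefficients[1]),
                 efficiency = unname(efficiency), r2 = r2,
                 n_points = sum(ok)),
            class = "standard_curve")
}

#' Interpolate relative input quantity from a Ct value
#'
#' Inverts the fitted standard curve; an undetected well (missing Ct) maps
#' to quantity 0.
#'
#' @param ct Ct value(s); `NA` = undetected.
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @return Relative quantity (1 at the curve's top standard).
#' @export
quantity_from_ct <- function(ct, curve) {
  q <- exp((ct - curve$intercept) / curve$slope)
  q[is.na(ct)] <- 0
  q
}

#' Percent of methylated reference (PMR)
#'
#' `PMR = 100 * (target/reference)_sample / (target/reference)_control`,
#' where the control is fully methylated (M.SssI-treated) DNA. A target
#' quantity of 0 gives PMR 0; a zero reference quantity leaves PMR
#' undefined (`NA`), mirroring samples whose Ct could not be detected.
#'
#' @param target_q,ref_q Sample target/reference quantities (vectors).
#' @param control_target_q,control_ref_q Control quantities (scalars > 0).
#' @return Numeric PMR values.
#' @export
compute_pmr <- function(target_q, ref_q, control_target_q, control_ref_q) {
  assert_that(control_ref_q > 0 && control_target_q > 0,
              "control quantities must be positive")
  control_ratio <- control_target_q / control_ref_q
  pmr <- rep(NA_real_, length(target_q))
  ok <- !is.na(ref_q) & ref_q > 0 & !is.na(target_q)
  pmr[ok] <- 100 * (target_q[ok] / ref_q[ok]) / control_ratio
  if (any(!ok))
    warnf("%d sample(s) with undefined PMR (missing or zero reference)",
          sum(!ok))
  pmr
}

#' ROC threshold closest to the top-left corner
#'
#' Evaluates candidate cutpoints at midpoints between sorted distinct
#' values and picks the one minimizing
#' `(1 - sensitivity)^2 + (1 - specificity)^2`, breaking ties toward
#' higher specificity. The orientation (whether low or high values
#' indicate the positive class) is chosen to give AUC >= 0.5.
#'
#' @param values Numeric marker values (e.g. PMR).
#' @param labels Binary truth (1/TRUE = positive class).
#' @return A list with `threshold`, `direction` (`"<="` if positives lie
#'   below the threshold, `">="` otherwise), `sensitivity`, `specificity`,
#'   and `auc`.
#' @export
closest_topleft_threshold <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  assert_that(any(labels == 1L) && any(labels == 0L),
              "both classes must be present")
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  if (length(unique(values)) == 1L) {
    warnf("constant marker values: degenerate ROC")
    return(list(threshold = values[1], direction = ">=",
                sensitivity = 1, specificity = 0, auc = 0.5))
  }
  auc_hi <- roc_auc(values, labels)$auc
  direction <- if (auc_hi >= 0.5) ">=" else "<="
  score <- if (direction == ">=") values else -values
  pos <- score[labels == 1L]; neg <- score[labels == 0L]

  sv <- sort(unique(score))
  cand <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  dist2 <- (1 - sens)^2 + (1 - spec)^2
  best <- which(dist2 == min(dist2))
  best <- best[which.max(spec[best])]
  thr <- if (direction == ">=") cand[best] else -cand[best]
  list(threshold = thr, direction = direction,
       sensitivity = sens[best], specificity = spec[best],
       auc = max(auc_hi, 1 - auc_hi))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration of the null distribution of the rank sum when the
#' pooled sample is small (`n_a + n_b <= 12`) and tie-free; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @param exact_max Largest pooled size for exact enumeration.
#' @return A list with `U` (Mann-Whitney statistic of group `a`), `p`
#'   (two-sided), and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  assert_that(length(a) >= 1L && length(b) >= 1L,
              "both groups must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (n <= exact_max && !has_ties) {
    # enumerate every assignment of ranks to group a
    combos <- utils::combn(n, na)
    u_all <- colSums(matrix(r[as.vector(combos)], nrow = na)) -
      na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    sigma2 <- na * nb / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    cc <- 0.5 * sign(U - mu)
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = U, p = p, method = method)
}

#' Analyze a MethyLight plate end-to-end
#'
#' Fits per-assay standard curves from the dilution wells, interpolates
#' all sample and control Ct values to relative quantities, and computes
#' PMR for every sample against the fully methylated control.
#'
#' @param wells Plate `data.frame` with columns `sample_id`, `role`,
#'   `group`, `assay`, `ct` (see [generate_methylight_plate()]).
#' @param dilution_factor Fold dilution of the standard series.
#' @return A list with `pmr` (`data.frame`: sample_id, group, target_q,
#'   ref_q, pmr), `curves` (per-assay `standard_curve`s), `control_pmr`,
#'   and `excluded` (samples with undefined PMR).
#' @export
quantify_plate <- function(wells, dilution_factor = 4) {
  assert_that(all(c("sample_id", "role", "assay", "ct") %in% colnames(wells)),
              "wells must have sample_id, role, assay, ct columns")
  ctrl <- wells[wells$role == "methylated_control", ]
  if (nrow(ctrl) == 0L)
    stopf("fully methylated (M.SssI) control missing: PMR undefined")

  std <- wells[wells$role == "standard", ]
  assert_that(nrow(std) > 0L, "standard dilution series missing")
  curves <- lapply(split(std, std$assay), function(s) {
    s <- s[order(s$sample_id), ]
    fit_standard_curve(s$ct, dilution_factor = dilution_factor)
  })

  q_of <- function(sample_id, assay) {
    w <- wells[wells$sample_id == sample_id & wells$assay == assay, ]
    if (nrow(w) == 0L) return(NA_real_)
    mean(quantity_from_ct(w$ct, curves[[assay]]))
  }
  ctrl_t <- q_of(ctrl$sample_id[1], "target")
  ctrl_r <- q_of(ctrl$sample_id[1], "reference")

  samp <- unique(wells[wells$role == "sample", c("sample_id", "group")])
  target_q <- vapply(samp$sample_id, q_of, numeric(1), assay = "target")
  ref_q <- vapply(samp$sample_id, q_of, numeric(1), assay = "reference")
  pmr <- suppressWarnings(compute_pmr(target_q, ref_q, ctrl_t, ctrl_r))
  # samples whose target reaction never amplified are excluded from group
  # comparisons (a truly-zero and a failed reaction are indistinguishable),
  # as are samples with an undefined (missing-reference) PMR
  target_na <- vapply(samp$sample_id, function(sid) {
    w <- wells[wells$sample_id == sid & wells$assay == "target", ]
    nrow(w) > 0L && all(is.na(w$ct))
  }, logical(1))
  undefined <- is.na(pmr) | target_na

  res <- data.frame(sample_id = samp$sample_id, group = samp$group,
                    target_q = target_q, ref_q = ref_q, pmr = pmr,
                    stringsAsFactors = FALSE)
  control_pmr <- 100 * (ctrl_t / ctrl_r) / (ctrl_t / ctrl_r)
  list(pmr = res, curves = curves, control_pmr = control_pmr,
       excluded = samp$sample_id[undefined])
}
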