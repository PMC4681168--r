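# Nearest-shrunken-centroid classification with nested leave-one-out
# cross-validation: DMP selection is repeated inside every fold so the
# held-out sample never informs feature selection.

#' Train a nearest shrunken centroid classifier
#'
#' Standardized class-centroid differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)` are soft-thresholded at `delta`,
#' `d'_ik = sign(d_ik) (|d_ik| - delta)_+`, and the shrunken centroids are
#' `xbar_i + m_k (s_i + s0) d'_ik`. `s_i` is the pooled within-class
#' standard deviation and `s0` its median across features.
#'
#' @param X Samples x features matrix.
#' @param y Class labels (two classes required).
#' @param delta Shrinkage threshold (default 1).
#' @param priors Named class priors; default class frequencies.
#' @param mk_convention `"pamr"` for `sqrt(1/n_k - 1/n)` or `"plus"` for
#'   `sqrt(1/n_k + 1/n)`.
#' @return A list of class `nsc_model` with centroids, shrunken
#'   differences, scales, priors and the selected (surviving) features.
#' @export
train_nsc <- function(X, y, delta = 1, priors = NULL,
                      mk_convention = c("pamr", "plus")) {
  mk_convention <- match.arg(mk_convention)
  y <- factor(y)
  assert_that(nlevels(y) == 2L, "exactly two classes are required")
  assert_that(ncol(X) >= 1L, "at least one feature is required")
  n <- nrow(X)
  classes <- levels(y)
  n_k <- table(y)
  assert_that(all(n_k >= 1L), "both classes must be present")

  xbar <- colMeans(X)
  xbar_k <- rbind(colMeans(X[y == classes[1], , drop = FALSE]),
                  colMeans(X[y == classes[2], , drop = FALSE]))
  rownames(xbar_k) <- classes

  # pooled within-class variance per feature
  ss <- numeric(ncol(X))
  for (k in classes) {
    Xk <- X[y == k, , drop = FALSE]
    ss <- ss + colSums((Xk - matrix(xbar_k[k, ], nrow(Xk), ncol(Xk),
                                    byrow = TRUE))^2)
  }
  s <- sqrt(ss / (n - 2L))
  s0 <- stats::median(s)

  m_k <- if (mk_convention == "pamr") sqrt(1 / n_k - 1 / n)
         else sqrt(1 / n_k + 1 / n)
  d <- sweep(sweep(xbar_k, 2L, xbar, "-"), 2L, s + s0, "/") / as.numeric(m_k)
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  centroids <- sweep(sweep(d_shrunk * as.numeric(m_k), 2L, s + s0, "*"),
                     2L, xbar, "+")

  if (is.null(priors)) priors <- as.numeric(n_k) / n
  priors <- stats::setNames(as.numeric(priors), classes)
  selected <- colnames(X)[colSums(d_shrunk != 0) > 0]
  structure(list(classes = classes, features = colnames(X),
                 overall_centroid = xbar, class_centroids = xbar_k,
                 shrunken_centroids = centroids, d = d, d_shrunk = d_shrunk,
                 s = s, s0 = s0, m_k = m_k, n_k = as.numeric(n_k),
                 priors = priors, delta = delta, selected = selected),
            class = "nsc_model")
}

#' Predict with a nearest shrunken centroid classifier
#'
#' Discriminant score for class k:
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`;
#' the predicted class minimizes it, and the reported posterior score is
#' the softmax of `-delta_k / 2` for `positive_class`.
#'
#' @param model An `nsc_model` from [train_nsc()].
#' @param x Named feature vector, or a samples x features matrix.
#' @param positive_class Class whose posterior score is reported
#'   (default `"severe"` when present, else the second class).
#' @return A list with `class` (predicted label(s)), `score` (posterior of
#'   the positive class), and `discriminant` (matrix of delta_k values).
#' @export
predict_nsc <- function(model, x, positive_class = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  assert_that(all(model$features %in% colnames(x)),
              "missing feature values for prediction")
  x <- x[, model$features, drop = FALSE]
  assert_that(!anyNA(x), "missing feature values for prediction")
  if (is.null(positive_class))
    positive_class <- if ("severe" %in% model$classes) "severe"
                      else model$classes[2]

  scale2 <- (model$s + model$s0)^2
  disc <- sapply(model$classes, function(k) {
    dev <- sweep(x, 2L, model$shrunken_centroids[k, ], "-")
    rowSums(sweep(dev^2, 2L, scale2, "/")) - 2 * log(model$priors[k])
  })
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1L,
                                         dimnames = list(NULL, model$classes))
  pred <- model$classes[max.col(-disc, ties.method = "first")]
  # softmax of -delta/2, numerically stabilized
  h <- -disc / 2
  h <- h - apply(h, 1L, max)
  post <- exp(h) / rowSums(exp(h))
  list(class = pred, score = unname(post[, positive_class]),
       discriminant = disc)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney pairwise-concordance probability (ties counted
#' one half); the 95% CI uses DeLong's variance estimator.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary truth (1/TRUE = positive class).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `auc`, `ci` (length 2), `var`, and `roc` (a
#'   `data.frame` of threshold/sensitivity/specificity points).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(as.logical(labels))
  assert_that(any(labels == 1L) && any(labels == 0L),
              "both classes must be present")
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)

  # Mann-Whitney via midranks
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)

  # DeLong structural components
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  V10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  V01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  s10 <- if (m > 1) stats::var(V10) else 0
  s01 <- if (n > 1) stats::var(V01) else 0
  v <- s10 / m + s01 / n
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * sqrt(v)))

  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1))),
    specificity = c(1, vapply(thr, function(t) mean(neg < t), numeric(1))))
  list(auc = auc, ci = ci, var = v, roc = roc)
}

#' Nested leave-one-out cross-validation of the epigenetic classifier
#'
#' In each iteration one sample is held out; DMP selection (covariate-
#' adjusted moderated-t analysis with Bonferroni and delta-beta filters)
#' is rerun on the remaining samples only; significant DMPs, ranked by
#' p-value, train a nearest shrunken centroid classifier which then scores
#' the held-out sample. Held-out scores are pooled into a single ROC with
#' a DeLong AUC confidence interval. Iterations selecting zero DMPs score
#' the held-out sample at the training prior of the severe class (and are
#' logged). Per-probe recurrence counts how many iterations selected each
#' probe.
#'
#' @param beta Beta matrix (probes x samples), already filtered/adjusted.
#' @param sample_sheet Sample sheet incl. covariates and cell proportions.
#' @param alpha,min_abs_delta DMP selection thresholds.
#' @param delta NSC shrinkage threshold (default 1).
#' @param max_dmps Optional cap on the number of (p-ranked) DMPs per fold.
#' @param celltypes Passed to [build_design_matrix()].
#' @return A list of class `loocv_report`: `predictions` (per held-out
#'   sample: truth, predicted, score, n DMPs), `auc`, `auc_ci`, `roc`,
#'   `recurrence`, `n_iterations`, `zero_dmp_iterations`,
#'   `mean_training_auc`.
#' @export
loocv_evaluate <- function(beta, sample_sheet, alpha = 0.05,
                           min_abs_delta = 0.05, delta = 1,
                           max_dmps = NULL, celltypes = NULL) {
  n <- ncol(beta)
  assert_that(identical(colnames(beta), sample_sheet$sample_id),
              "sample_sheet rows must align with beta columns")
  assert_that(min(table(sample_sheet$group)) >= 2L,
              "need at least 2 samples per class")

  recurrence <- integer(0)
  preds <- vector("list", n)
  train_auc <- rep(NA_real_, n)
  zero_iter <- character(0)
  # Non-informative fallback score for zero-DMP folds. It must be the
  # same constant in every fold: the per-fold training prevalence differs
  # across folds only through the held-out label (8/(n-1) vs 9/(n-1)),
  # which would anti-rank the held-out samples and bias a null AUC to 0.
  prior_severe <- mean(sample_sheet$group == "severe")
  majority_class <- names(which.max(table(sample_sheet$group)))

  for (i in seq_len(n)) {
    tr_beta <- beta[, -i, drop = FALSE]
    tr_sheet <- sample_sheet[-i, , drop = FALSE]
    res <- run_dmp_analysis(tr_beta, tr_sheet, alpha = alpha,
                            min_abs_delta = min_abs_delta,
                            celltypes = celltypes)
    dmp_ids <- res$dmps$probe_id  # already ranked by p
    if (!is.null(max_dmps) && length(dmp_ids) > max_dmps)
      dmp_ids <- dmp_ids[seq_len(max_dmps)]

    if (length(dmp_ids) == 0L) {
      zero_iter <- c(zero_iter, sample_sheet$sample_id[i])
      score <- prior_severe
      pred_class <- majority_class
    } else {
      for (id in dmp_ids) {
        recurrence[id] <- (if (is.na(recurrence[id])) 0L
                           else recurrence[id]) + 1L
      }
      model <- train_nsc(t(tr_beta[dmp_ids, , drop = FALSE]),
                         tr_sheet$group, delta = delta)
      pr <- predict_nsc(model, beta[dmp_ids, i])
      score <- pr$score
      pred_class <- pr$class
      tr_pred <- predict_nsc(model, t(tr_beta[dmp_ids, , drop = FALSE]))
      if (length(unique(tr_sheet$group)) == 2L &&
          length(unique(tr_pred$score)) > 1L)
        train_auc[i] <- roc_auc(tr_pred$score,
                                tr_sheet$group == "severe")$auc
    }
    preds[[i]] <- data.frame(sample_id = sample_sheet$sample_id[i],
                             truth = sample_sheet$group[i],
                             predicted = pred_class, score = score,
                             n_dmps = length(dmp_ids),
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  pooled <- roc_auc(predictions$score, predictions$truth == "severe")
  structure(list(predictions = predictions, auc = pooled$auc,
                 auc_ci = pooled$ci, roc = pooled$roc,
                 recurrence = recurrence, n_iterations = n,
                 zero_dmp_iterations = zero_iter,
                 mean_training_auc = mean(train_auc, na.rm = TRUE)),
            class = "loocv_report")
}

#' Rank DMPs by cross-validation recurrence
#'
#' Orders the full-data DMPs by how often each was selected across LOOCV
#' iterations (descending), breaking ties by descending absolute
#' delta-beta — the ranking rule behind a recurrence-annotated DMP table.
#'
#' @param report A `loocv_report` from [loocv_evaluate()].
#' @param full_data_dmps A `dmp_result` from the full-cohort analysis.
#' @return The DMP table with columns `recurrence` and `rank` added,
#'   reordered accordingly.
#' @export
rank_dmp_recurrence <- function(report, full_data_dmps) {
  if (nrow(full_data_dmps) == 0L) {
    full_data_dmps$recurrence <- integer()
    return(full_data_dmps)
  }
  rec <- report$recurrence[full_data_dmps$probe_id]
  rec[is.na(rec)] <- 0L
  out <- full_data_dmps
  out$recurrence <- as.integer(rec)
  ord <- order(-out$recurrence, -abs(out$delta_beta))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
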