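# Shrunken-centroid classifier, ROC/AUC, nested LOOCV, recurrence ranking.

test_that("train_nsc matches direct scalar evaluation of the formulas", {
  toy <- nsc_toy()
  for (delta in c(0, 0.5, 1)) {
    model <- train_nsc(toy$X, toy$y, delta = delta)
    oracle <- nsc_oracle(toy$X, toy$y, delta)
    expect_equal(unname(model$d), unname(oracle$d), tolerance = 1e-12)
    expect_equal(unname(model$d_shrunk), unname(oracle$d_shrunk),
                 tolerance = 1e-12)
    expect_equal(unname(model$shrunken_centroids),
                 unname(oracle$centroids), tolerance = 1e-12)
  }
})

test_that("shrinkage limits: delta = 0 and total shrinkage", {
  toy <- nsc_toy(seed = 2)
  m0 <- train_nsc(toy$X, toy$y, delta = 0)
  expect_equal(m0$shrunken_centroids, m0$class_centroids,
               tolerance = 1e-12)

  big <- max(abs(train_nsc(toy$X, toy$y, delta = 0)$d)) + 1
  mb <- train_nsc(toy$X, toy$y, delta = big)
  expect_equal(unname(mb$shrunken_centroids[1, ]),
               unname(mb$overall_centroid), tolerance = 1e-12)
  pr <- predict_nsc(mb, toy$X[1, ])
  expect_equal(pr$score, unname(mb$priors["severe"]), tolerance = 1e-12)

  expect_error(train_nsc(toy$X, rep("severe", 8)), "two classes")
})

test_that("predict_nsc: centroid identity, prior tiebreak, formula oracle", {
  toy <- nsc_toy(seed = 3)
  model <- train_nsc(toy$X, toy$y, delta = 0.3)
  pr <- predict_nsc(model, model$shrunken_centroids["severe", ])
  expect_identical(pr$class, "severe")

  # fully shrunk => every x is equidistant; skewed priors decide
  big <- max(abs(model$d)) + 1
  mb <- train_nsc(toy$X, toy$y, delta = big,
                  priors = c(no_mild = 0.9, severe = 0.1))
  prb <- predict_nsc(mb, toy$X[5, ])
  expect_identical(prb$class, "no_mild")

  # brute-force discriminant evaluation
  x <- toy$X[2, ]
  disc_oracle <- sapply(model$classes, function(k) {
    sum((x - model$shrunken_centroids[k, ])^2 / (model$s + model$s0)^2) -
      2 * log(model$priors[[k]])
  })
  pr2 <- predict_nsc(model, x)
  expect_equal(unname(pr2$discriminant[1, ]), unname(disc_oracle),
               tolerance = 1e-12)
  h <- -disc_oracle / 2
  h <- h - max(h)  # the softmax is shift-invariant; avoid underflow
  expect_equal(pr2$score, unname(exp(h["severe"]) / sum(exp(h))),
               tolerance = 1e-12)

  expect_error(predict_nsc(model, x[-1]), "missing feature")
})

test_that("NSC with delta 0 and equal priors is nearest-centroid in scaled space", {
  toy <- nsc_toy(seed = 4, n = 12, m = 6)
  model <- train_nsc(toy$X, toy$y, delta = 0,
                     priors = c(no_mild = 0.5, severe = 0.5))
  for (i in 1:6) {
    x <- toy$X[i, ]
    dists <- sapply(model$classes, function(k)
      sum(((x - model$class_centroids[k, ]) / (model$s + model$s0))^2))
    expect_identical(predict_nsc(model, x)$class,
                     names(which.min(dists)))
  }
})

test_that("roc_auc equals exhaustive pairwise concordance with ties at half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))$auc, 1)
  set.seed(50)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), 2)  # rounding forces occasional ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(scores, labels)$auc,
                 conc / (length(pos) * length(neg)))
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(51)
  scores <- rnorm(30)
  labels <- rbinom(30, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(qnorm(pnorm(scores))^3 + 10, labels)$auc, a0)
})

test_that("DeLong interval behaves sensibly on a known configuration", {
  set.seed(52)
  scores <- c(rnorm(40, 1), rnorm(40, 0))
  labels <- rep(c(1, 0), each = 40)
  r <- roc_auc(scores, labels)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_true(all(r$ci >= 0 & r$ci <= 1))
  # perfect separation: zero variance, degenerate interval at 1
  rp <- roc_auc(c(2, 3, 4, -1, -2, -3), c(1, 1, 1, 0, 0, 0))
  expect_equal(rp$auc, 1)
  expect_equal(rp$ci, c(1, 1))
})

test_that("LOOCV separates a strong-signal cohort and bounds recurrence", {
  co <- small_cohort(seed = 60, n_probes = 600,
                     delta_beta_range = c(0.25, 0.3), noise_sd = 0.01)
  props <- estimate_cell_proportions(co$beta, co$reference)
  sheet <- add_cell_proportions(co$sample_sheet, props)
  rep <- loocv_evaluate(co$beta, sheet)
  expect_equal(rep$auc, 1)
  expect_identical(rep$n_iterations, 85L)
  expect_true(all(rep$recurrence <= 85L))
  # planted probes with huge effects are selected in every iteration
  planted <- names(co$truth$planted_dmp_delta)
  expect_true(any(rep$recurrence[planted] == 85L))
  expect_identical(nrow(rep$predictions), 85L)
})

test_that("feature selection inside the fold avoids the leakage inflation", {
  co <- null_cohort(seed = 61, n_probes = 500, n_samples = 40L,
                    n_severe = 12L)
  # leaky protocol: select top probes on ALL data, then cross-validate
  res <- run_dmp_analysis(co$beta, co$sample_sheet)
  top <- names(sort(res$stats$p))[1:20]
  scores <- numeric(40)
  for (i in 1:40) {
    model <- train_nsc(t(co$beta[top, -i, drop = FALSE]),
                       co$sample_sheet$group[-i], delta = 0)
    scores[i] <- predict_nsc(model, co$beta[top, i])$score
  }
  leaky_auc <- roc_auc(scores, co$sample_sheet$group == "severe")$auc
  expect_gt(leaky_auc, 0.65)  # selection leakage visibly inflates the AUC
})

test_that("rank_dmp_recurrence orders by recurrence then |delta beta|", {
  dmps <- data.frame(rank = 1:3, probe_id = c("a", "b", "c"),
                     p = c(1e-6, 1e-7, 1e-8),
                     p_bonferroni = c(1e-3, 1e-4, 1e-5),
                     delta_beta = c(-0.162, -0.180, -0.129),
                     group_coef = c(-0.15, -0.17, -0.12),
                     stringsAsFactors = FALSE)
  class(dmps) <- c("dmp_result", "data.frame")
  report <- list(recurrence = c(a = 85L, b = 85L, c = 82L))
  ranked <- rank_dmp_recurrence(report, dmps)
  expect_identical(ranked$probe_id, c("b", "a", "c"))
  expect_identical(ranked$rank, 1:3)

  # all-equal recurrence: ordering purely by |delta beta|
  report2 <- list(recurrence = c(a = 10L, b = 10L, c = 10L))
  ranked2 <- rank_dmp_recurrence(report2, dmps)
  expect_identical(ranked2$probe_id, c("b", "a", "c"))

  empty <- dmps[0, ]
  class(empty) <- c("dmp_result", "data.frame")
  expect_identical(nrow(rank_dmp_recurrence(report, empty)), 0L)
})
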