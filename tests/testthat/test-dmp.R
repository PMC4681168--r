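# Per-probe models, variance moderation, DMP selection.

simple_design <- function(group, sex = NULL, age = NULL) {
  n <- length(group)
  if (is.null(sex)) sex <- rep_len(c("M", "M", "F", "F"), n)
  if (is.null(age)) age <- seq(25, 65, length.out = n)
  sheet <- data.frame(sample_id = sprintf("S%02d", 1:n), group = group,
                      sex = sex, age_years = age,
                      stringsAsFactors = FALSE)
  build_design_matrix(sheet)
}

test_that("fit_probe_models: constants, exact means, lm oracle", {
  grp <- rep(c("severe", "no_mild"), each = 6)
  X <- simple_design(grp, sex = rep(c("M", "F"), 6),
                     age = runif(12, 20, 60))

  beta <- toy_beta(0.42, 3, 12)
  fit <- fit_probe_models(beta, X)
  expect_equal(unname(fit$group_coef), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(fit$s2), rep(0, 3), tolerance = 1e-12)

  # two-group toy with no other covariates: coefficient = mean difference
  grp6 <- rep(c("severe", "no_mild"), each = 3)
  X2 <- cbind(intercept = 1, group_severe = as.integer(grp6 == "severe"))
  attr(X2, "group_col") <- "group_severe"
  b2 <- toy_beta(rep(c(0.5, 0.2), each = 3), 1, 6)
  fit2 <- fit_probe_models(b2, X2)
  expect_equal(unname(fit2$group_coef), 0.3, tolerance = 1e-12)

  # random instance vs lm()
  set.seed(20)
  b3 <- toy_beta(runif(20 * 12, 0.1, 0.9), 20, 12)
  fit3 <- fit_probe_models(b3, X)
  for (g in c(1, 7, 20)) {
    lmfit <- lm(b3[g, ] ~ 0 + X)
    expect_equal(unname(fit3$coef[g, ]), unname(coef(lmfit)),
                 tolerance = 1e-10)
    expect_equal(unname(fit3$s2[g]), sum(resid(lmfit)^2) / fit3$df,
                 tolerance = 1e-10)
  }

  X_bad <- cbind(X, dup = X[, "group_severe"])
  expect_error(fit_probe_models(b3, X_bad), "rank-deficient")
})

test_that("moderate_variances limits behave as specified", {
  set.seed(30)
  s2 <- rchisq(50, 10) / 10 * 0.01
  # equal variances: nothing to shrink, posterior equals the common value
  mo_eq <- moderate_variances(rep(0.02, 50), df = 10)
  expect_equal(unname(mo_eq$s2_post), rep(0.02, 50), tolerance = 1e-12)

  # d0 = 0: no moderation
  mo0 <- moderate_variances(s2, df = 10, d0_override = 0)
  expect_identical(unname(mo0$s2_post), unname(s2))

  # d0 = Inf: complete shrinkage to the prior
  moI <- moderate_variances(s2, df = 10, d0_override = Inf)
  expect_equal(unname(moI$s2_post), rep(moI$s0_2, 50))

  expect_warning(moderate_variances(s2[1:5], df = 10), "fewer than 10")
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(11)
  m <- 400; n <- 24
  s2_true <- 4e-4 * 8 / rchisq(m, 8)
  beta <- toy_beta(0.5 + rnorm(m * n, 0, rep(sqrt(s2_true), n)), m, n)
  X <- simple_design(rep(c("severe", "no_mild"), n / 2),
                     age = runif(n, 20, 60))
  fit <- fit_probe_models(beta, X)
  st <- moderated_t_stats(fit)
  eb <- limma::eBayes(limma::lmFit(beta, X))
  expect_equal(st$d0, eb$df.prior, tolerance = 1e-9)
  expect_equal(st$s0_2, eb$s2.prior, tolerance = 1e-9)
  expect_equal(unname(st$t), unname(eb$t[, "group_severe"]),
               tolerance = 1e-9)
  expect_equal(unname(st$p), unname(eb$p.value[, "group_severe"]),
               tolerance = 1e-9)
})

test_that("select_dmps applies both thresholds and sorts by p", {
  p <- c(a = 1e-6, b = 2e-8, c = 0.5, d = 1e-7)
  stats <- structure(list(p = p, p_bonferroni = pmin(1, p * 4),
                          group_coef = c(0.1, 0.03, 0.2, -0.18)),
                     class = "moderated_stats")
  delta <- c(a = 0.10, b = 0.03, c = 0.20, d = -0.18)
  res <- select_dmps(stats, delta)
  # b fails the effect-size filter despite tiny p; c fails significance
  expect_identical(res$probe_id, c("d", "a"))
  expect_identical(res$rank, 1:2)
  expect_true(all(res$p_bonferroni < 0.05 & abs(res$delta_beta) >= 0.05))

  empty <- select_dmps(stats, delta, alpha = 1e-12)
  expect_identical(nrow(empty), 0L)
})

test_that("Bonferroni adjustment is monotone and capped at 1", {
  set.seed(31)
  p <- sort(runif(50))
  stats <- structure(list(p = p, p_bonferroni = pmin(1, p * 50),
                          group_coef = rep(0.1, 50)),
                     class = "moderated_stats")
  expect_true(all(diff(stats$p_bonferroni) >= 0))
  expect_true(all(stats$p_bonferroni <= 1))
  # moderated p decreases strictly in |t| at fixed df
  tt <- seq(0.1, 5, by = 0.1)
  pp <- 2 * pt(-tt, df = 20)
  expect_true(all(diff(pp) < 0))
})

test_that("family-wise any-discovery rate is controlled under the null", {
  m <- 5000L; n <- 30L
  discoveries <- logical(20)
  for (s in 1:20) {
    set.seed(400 + s)
    beta <- toy_beta(0.5 + rnorm(m * n, 0, 0.02), m, n)
    X <- simple_design(sample(rep(c("severe", "no_mild"), n / 2)),
                       age = runif(n, 20, 60))
    fit <- fit_probe_models(beta, X)
    st <- moderated_t_stats(fit)
    grp <- ifelse(X[, "group_severe"] == 1, "severe", "no_mild")
    delta <- compute_delta_beta(beta, grp)
    res <- select_dmps(st, delta)
    discoveries[s] <- nrow(res) > 0
  }
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / 20)
  expect_lte(mean(discoveries), bound)
})

test_that("cell covariates reduce spurious discoveries under confounding", {
  n_with <- integer(5); n_without <- integer(5)
  for (s in 1:5) {
    co <- null_cohort(seed = 600 + s, n_probes = 800,
                      confound_cells_with_group = TRUE)
    props <- estimate_cell_proportions(co$beta, co$reference)
    sheet <- add_cell_proportions(co$sample_sheet, props)
    # compare discovery counts at a permissive threshold
    with_cells <- run_dmp_analysis(co$beta, sheet, alpha = 0.25,
                                   min_abs_delta = 0)
    without_cells <- run_dmp_analysis(co$beta, co$sample_sheet,
                                      alpha = 0.25, min_abs_delta = 0)
    n_with[s] <- nrow(with_cells$dmps)
    n_without[s] <- nrow(without_cells$dmps)
  }
  expect_lte(median(n_with), median(n_without))
})
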