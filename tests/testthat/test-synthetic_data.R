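# Generator contracts: determinism, planted structure, QC plumbing.

test_that("annotation generator: empty case, determinism, spacing geometry", {
  cfg0 <- cohort_config(n_probes = 0L, seed = 1)
  expect_identical(nrow(generate_annotation(cfg0)), 0L)

  cfg <- cohort_config(n_probes = 1000L, seed = 1)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)

  # within-cluster spacing <= 500 bp; between-cluster gaps >= 5 kb
  for (ch in unique(a1$chrom)) {
    sub <- a1[a1$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    if (nrow(sub) < 2L) next
    gaps <- diff(sub$pos)
    same_cluster <- diff(sub$cluster_id) == 0L
    expect_true(all(gaps[same_cluster] <= 500))
    expect_true(all(gaps[!same_cluster] >= 5000))
  }
  expect_true(all(a1$feature %in% c("TSS200", "TSS1500", "5'UTR", "1stExon",
                                    "Body", "3'UTR", "IGR")))
  expect_true(all(a1$cpg_context %in% c("Island", "Shore", "Shelf", "none")))
})

test_that("annotation flag counts stay within binomial 99% bounds", {
  cfg <- cohort_config(n_probes = 1000L, frac_noncg = 0.05,
                       frac_ambiguous = 0.05, frac_snp = 0.05, seed = 2)
  ann <- generate_annotation(cfg)
  lo <- qbinom(0.005, 1000, 0.05)
  hi <- qbinom(0.995, 1000, 0.05)
  expect_gte(sum(ann$is_noncg), lo); expect_lte(sum(ann$is_noncg), hi)
  expect_gte(sum(ann$is_ambiguous), lo); expect_lte(sum(ann$is_ambiguous), hi)
  expect_gte(sum(ann$has_snp_at_cg), lo); expect_lte(sum(ann$has_snp_at_cg), hi)
})

test_that("cell reference: range, degenerate case, discriminating spread", {
  cfg <- cohort_config(n_probes = 800L, seed = 3)
  ann <- generate_annotation(cfg)
  ref <- generate_cell_reference(ann, cfg)
  expect_true(all(ref$profiles >= 0 & ref$profiles <= 1))
  expect_identical(ncol(ref$profiles), 6L)

  spread <- apply(ref$profiles[ref$discriminating, ], 1L,
                  function(x) max(x) - min(x))
  expect_true(all(spread >= 0.3))

  cfg1 <- cohort_config(n_probes = 100L, n_celltypes = 1L, seed = 3)
  ann1 <- generate_annotation(cfg1)
  ref1 <- generate_cell_reference(ann1, cfg1)
  expect_identical(ncol(ref1$profiles), 1L)
})

test_that("cohort generator is deterministic and respects ground-truth invariants", {
  co1 <- small_cohort(seed = 5)
  co2 <- small_cohort(seed = 5)
  expect_identical(co1$beta, co2$beta)
  expect_identical(co1$sample_sheet, co2$sample_sheet)
  expect_identical(co1$qc, co2$qc)

  expect_true(all(co1$beta >= 0 & co1$beta <= 1))
  expect_lt(max(abs(rowSums(co1$truth$true_cell_proportions) - 1)), 1e-12)
  mags <- abs(co1$truth$planted_dmp_delta)
  rng <- co1$config$delta_beta_range
  expect_true(all(mags >= rng[1] & mags <= rng[2]))
})

test_that("null construction: zero noise, no effects => identical group means", {
  cfg <- cohort_config(n_samples = 20L, n_severe = 5L, n_probes = 300L,
                       n_planted_dmps = 0L, n_cluster_dmps = 0L,
                       n_batches = 1L, noise_sd = 0,
                       age_effect_probes = 0L, sex_effect_probes = 0L,
                       n_celltypes = 1L, n_discriminating = 50L, seed = 7)
  co <- generate_cohort(cfg)
  d <- compute_delta_beta(co$beta, co$sample_sheet$group)
  expect_lt(max(abs(d)), 1e-12)
})

test_that("planted effects are analytically forced at zero noise", {
  cfg <- cohort_config(n_samples = 30L, n_severe = 9L, n_probes = 500L,
                       n_planted_dmps = 12L, n_cluster_dmps = 0L,
                       delta_beta_range = c(0.15, 0.15), n_batches = 1L,
                       noise_sd = 0, age_effect_probes = 0L,
                       sex_effect_probes = 0L, n_celltypes = 1L,
                       n_discriminating = 50L, seed = 8)
  co <- generate_cohort(cfg)
  d <- compute_delta_beta(co$beta, co$sample_sheet$group)
  planted <- co$truth$planted_dmp_delta
  expect_equal(unname(d[names(planted)]), unname(planted), tolerance = 1e-12)
  expect_lt(max(abs(d[setdiff(names(d), names(planted))])), 1e-12)
})

test_that("noisy cohort: empirical planted delta within standard-error bound", {
  co <- small_cohort(seed = 9)
  d <- compute_delta_beta(co$beta, co$sample_sheet$group)
  planted <- co$truth$planted_dmp_delta
  bound <- 3 * co$config$noise_sd / sqrt(co$config$n_severe)
  expect_true(all(abs(d[names(planted)] - planted) <= bound))
})

test_that("null group-difference z-scores are standard normal across seeds", {
  z_all <- numeric()
  for (s in 1:10) {
    co <- null_cohort(seed = 300 + s, n_probes = 400)
    grp <- co$sample_sheet$group
    # restrict to probes without cell-type contrast (pure noise there)
    keep <- setdiff(rownames(co$beta), co$reference$discriminating)
    d <- compute_delta_beta(co$beta[keep, ], grp)
    se <- co$config$noise_sd *
      sqrt(1 / sum(grp == "severe") + 1 / sum(grp != "severe"))
    z_all <- c(z_all, d / se)
  }
  ks <- suppressWarnings(ks.test(z_all, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort rejects planted/flagged overlap configurations", {
  # flag everything: no clean probes left to plant on
  cfg <- cohort_config(n_probes = 200L, n_planted_dmps = 5L,
                       n_cluster_dmps = 0L, frac_noncg = 1, seed = 10)
  expect_error(generate_cohort(cfg), "plant")
})

test_that("methylight plate generator: determinism and exact identities", {
  pc <- plate_config(seed = 4)
  p1 <- generate_methylight_plate(pc)
  p2 <- generate_methylight_plate(pc)
  expect_identical(p1$wells, p2$wells)
  expect_true(all(p1$wells$ct > 0 | is.na(p1$wells$ct)))

  pc0 <- plate_config(ct_noise_sd = 0, efficiency = 2, dilution_factor = 4,
                      seed = 4)
  p0 <- generate_methylight_plate(pc0)
  std <- p0$wells[p0$wells$role == "standard" & p0$wells$assay == "target", ]
  std <- std[order(std$sample_id), ]
  expect_equal(diff(std$ct), rep(2, nrow(std) - 1L), tolerance = 1e-12)

  # negative and non-template controls never amplify
  expect_true(all(is.na(p0$wells$ct[p0$wells$role == "ntc"])))
  expect_true(is.na(p0$wells$ct[p0$wells$role == "negative_control" &
                                  p0$wells$assay == "target"]))
})
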