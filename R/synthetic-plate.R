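#' Configuration for a synthetic MethyLight qPCR plate
#'
#' Defaults emulate a clinical replication experiment: 63 donors (9 matched
#' to severe aGVHD, 54 to no/mild), a 4-fold serial dilution of a fully
#' methylated (M.SssI-treated) standard over five points, perfect
#' amplification efficiency 2, and mild Ct noise.
#'
#' @param n_samples_per_group Named counts, e.g. `c(severe = 9, no_mild = 54)`.
#' @param true_pmr_by_group Named mean percent-methylated-reference (PMR)
#'   per group; severe donors are hypomethylated at the target locus, hence
#'   the lower default.
#' @param pmr_sdlog Log-scale std. dev. of per-sample true PMR around the
#'   group mean (PMR values are strongly right-skewed in practice).
#' @param dilution_factor Fold change between consecutive standards.
#' @param n_dilution_points Number of standard-curve points.
#' @param ct_noise_sd Gaussian noise on Ct values, in cycles.
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @param intercept Ct of the undiluted standard (quantity 1).
#' @param n_undetected Number of samples whose target reaction fails to
#'   amplify (Ct recorded as missing).
#' @param seed Integer seed.
#' @return A list of class `plate_config`.
#' @export
plate_config <- function(n_samples_per_group = c(severe = 9, no_mild = 54),
                         true_pmr_by_group = c(severe = 5, no_mild = 25),
                         pmr_sdlog = 0.8,
                         dilution_factor = 4,
                         n_dilution_points = 5L,
                         ct_noise_sd = 0.25,
                         efficiency = 2,
                         intercept = 25,
                         n_undetected = 0L,
                         seed = 1L) {
  assert_that(dilution_factor > 1, "dilution_factor must be > 1")
  assert_that(efficiency > 1 && efficiency <= 2,
              "efficiency must lie in (1, 2]")
  assert_that(all(n_samples_per_group > 0), "group sizes must be positive")
  assert_that(identical(sort(names(n_samples_per_group)),
                        sort(names(true_pmr_by_group))),
              "group names of sizes and PMR means must match")
  structure(list(n_samples_per_group = n_samples_per_group,
                 true_pmr_by_group = true_pmr_by_group,
                 pmr_sdlog = pmr_sdlog,
                 dilution_factor = dilution_factor,
                 n_dilution_points = as.integer(n_dilution_points),
                 ct_noise_sd = ct_noise_sd, efficiency = efficiency,
                 intercept = intercept,
                 n_undetected = as.integer(n_undetected),
                 seed = as.integer(seed)),
            class = "plate_config")
}

ct_from_quantity <- function(q, intercept, efficiency) {
  intercept - log(q) / log(efficiency)
}

#' Simulate a MethyLight plate with ground truth
#'
#' Generates well-level Ct values for a target CpG assay and a reference
#' (input-normalization) assay: per-sample wells, a fully methylated M.SssI
#' control (true PMR = 100), an unmethylated negative control and a
#' non-template control (no amplification, Ct missing), and a serial
#' dilution of the methylated standard for both assays. Ct follows
#' `intercept - log(quantity)/log(efficiency)` plus Gaussian noise.
#'
#' @param config A [plate_config()] object.
#' @return A list of class `methylight_plate` with elements `wells` (a
#'   `data.frame` with columns `well`, `sample_id`, `role`, `group`,
#'   `assay`, `ct`) and `truth` (per-sample true PMR and labels, curve
#'   parameters).
#' @export
generate_methylight_plate <- function(config) {
  set.seed(derive_seed(config$seed, 53L))
  groups <- names(config$n_samples_per_group)
  n_by_g <- config$n_samples_per_group
  n <- sum(n_by_g)
  sample_ids <- sprintf("S%03d", seq_len(n))
  group <- rep(groups, n_by_g)

  mu <- config$true_pmr_by_group[group]
  # lognormal around the group mean, mean-corrected so E[PMR] = group mean
  true_pmr <- stats::rlnorm(n, meanlog = log(mu) - config$pmr_sdlog^2 / 2,
                            sdlog = config$pmr_sdlog)
  names(true_pmr) <- sample_ids

  # relative input DNA varies by sample; PMR is a ratio of ratios and is
  # insensitive to it
  input <- stats::rlnorm(n, 0, 0.2)
  target_q <- input * true_pmr / 100
  ref_q <- input

  undet <- if (config$n_undetected > 0)
    sample.int(n, config$n_undetected) else integer()

  rows <- list()
  add <- function(sample_id, role, group, assay, q, detected = TRUE) {
    ct <- if (detected && q > 0)
      ct_from_quantity(q, config$intercept, config$efficiency) +
        stats::rnorm(1, 0, config$ct_noise_sd)
    else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, role = role, group = group, assay = assay,
      ct = ct, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    add(sample_ids[i], "sample", group[i], "target", target_q[i],
        detected = !(i %in% undet))
    add(sample_ids[i], "sample", group[i], "reference", ref_q[i])
  }
  add("M.SssI", "methylated_control", NA_character_, "target", 1)
  add("M.SssI", "methylated_control", NA_character_, "reference", 1)
  add("WGA", "negative_control", NA_character_, "target", 0, detected = FALSE)
  add("WGA", "negative_control", NA_character_, "reference", 1)
  add("NTC", "ntc", NA_character_, "target", 0, detected = FALSE)
  add("NTC", "ntc", NA_character_, "reference", 0, detected = FALSE)
  for (d in seq_len(config$n_dilution_points)) {
    q <- config$dilution_factor^(-(d - 1L))
    add(sprintf("STD%d", d), "standard", NA_character_, "target", q)
    add(sprintf("STD%d", d), "standard", NA_character_, "reference", q)
  }
  wells <- do.call(rbind, rows)
  wells$well <- sprintf("W%03d", seq_len(nrow(wells)))
  wells <- wells[, c("well", "sample_id", "role", "group", "assay", "ct")]

  truth <- list(true_pmr = true_pmr,
                group = stats::setNames(group, sample_ids),
                undetected_samples = sample_ids[undet],
                intercept = config$intercept,
                efficiency = config$efficiency)
  structure(list(wells = wells, truth = truth, config = config),
            class = "methylight_plate")
}
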