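#' Configuration for a synthetic methylation cohort
#'
#' Builds the parameter object consumed by [generate_annotation()],
#' [generate_cell_reference()] and [generate_cohort()]. Defaults emulate the
#' discovery cohort shape of a donor aGVHD-severity study: 85 donors of whom
#' 9 are matched to severe aGVHD recipients, two array slides (batches), a
#' six-cell-type blood mixture, and 30 planted differentially methylated
#' positions (DMPs) with group effects between 0.06 and 0.18 on the beta
#' scale.
#'
#' @param n_samples Total number of donor samples.
#' @param n_severe Number of samples in the "severe" group (must be
#'   smaller than `n_samples`).
#' @param n_probes Number of array probes to simulate.
#' @param n_celltypes Number of leukocyte cell types in the mixture model.
#' @param n_planted_dmps Number of probes carrying a true group effect.
#' @param delta_beta_range Length-2 interval inside (0, 1); magnitudes of
#'   planted group effects are drawn uniformly from it.
#' @param n_cluster_dmps How many of the planted DMPs are placed as one
#'   contiguous hypomethylated CpG-island run (emulating a multi-probe DMR);
#'   0 disables clustering.
#' @param n_batches Number of array slides (Sentrix-style batches).
#' @param batch_shift_sd Std. dev. of per-batch, per-probe location shifts
#'   on the beta scale.
#' @param batch_scale_sd Std. dev. of `log` per-batch noise scale factors.
#' @param noise_sd Std. dev. of additive Gaussian measurement noise on the
#'   beta scale.
#' @param age_range Length-2 donor age range in years.
#' @param age_effect_probes Number of probes with a linear age trend.
#' @param age_slope Beta change per year on age-affected probes.
#' @param sex_effect_probes Number of autosomal probes with a sex offset.
#' @param sex_offset Beta offset added to male samples on sex-affected probes.
#' @param confound_cells_with_group If `TRUE`, the severe group draws its
#'   cell mixture from a shifted Dirichlet (cell composition confounding).
#' @param island_cluster_size Number of probes per CpG-island-like cluster.
#' @param n_discriminating Number of probes whose reference profiles
#'   separate the cell types (used by deconvolution).
#' @param frac_noncg,frac_ambiguous,frac_snp Fractions of probes flagged as
#'   non-CG, ambiguously mapping, or carrying a SNP at the probed CG.
#' @param frac_sex Fraction of probe clusters placed on chrX/chrY.
#' @param qc_fail_frac Fraction of probes planted as QC failures (detection
#'   p-value or bead-count rule).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 85L,
                          n_severe = 9L,
                          n_probes = 20000L,
                          n_celltypes = 6L,
                          n_planted_dmps = 30L,
                          delta_beta_range = c(0.06, 0.18),
                          n_cluster_dmps = 4L,
                          n_batches = 2L,
                          batch_shift_sd = 0.02,
                          batch_scale_sd = 0.05,
                          noise_sd = 0.02,
                          age_range = c(14, 72),
                          age_effect_probes = 50L,
                          age_slope = 0.003,
                          sex_effect_probes = 50L,
                          sex_offset = 0.05,
                          confound_cells_with_group = FALSE,
                          island_cluster_size = 4L,
                          n_discriminating = 600L,
                          frac_noncg = 0.02,
                          frac_ambiguous = 0.02,
                          frac_snp = 0.02,
                          frac_sex = 0.03,
                          qc_fail_frac = 0.002,
                          seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_severe = as.integer(n_severe),
    n_probes = as.integer(n_probes), n_celltypes = as.integer(n_celltypes),
    n_planted_dmps = as.integer(n_planted_dmps),
    delta_beta_range = as.numeric(delta_beta_range),
    n_cluster_dmps = as.integer(n_cluster_dmps),
    n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    noise_sd = noise_sd, age_range = as.numeric(age_range),
    age_effect_probes = as.integer(age_effect_probes), age_slope = age_slope,
    sex_effect_probes = as.integer(sex_effect_probes), sex_offset = sex_offset,
    confound_cells_with_group = isTRUE(confound_cells_with_group),
    island_cluster_size = as.integer(island_cluster_size),
    n_discriminating = as.integer(n_discriminating),
    frac_noncg = frac_noncg, frac_ambiguous = frac_ambiguous,
    frac_snp = frac_snp, frac_sex = frac_sex,
    qc_fail_frac = qc_fail_frac, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  assert_that(cfg$n_severe < cfg$n_samples, "n_severe must be < n_samples")
  counts <- c(cfg$n_samples, cfg$n_severe, cfg$n_celltypes,
              cfg$n_batches, cfg$island_cluster_size)
  assert_that(all(counts > 0L), "all counts must be positive")
  assert_that(cfg$n_probes >= 0L, "n_probes must be nonnegative")
  rng <- cfg$delta_beta_range
  assert_that(length(rng) == 2L && rng[1] <= rng[2] &&
                rng[1] > 0 && rng[2] < 1,
              "delta_beta_range must be an interval inside (0, 1)")
  assert_that(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(cfg$n_cluster_dmps <= cfg$n_planted_dmps,
              "n_cluster_dmps cannot exceed n_planted_dmps")
  invisible(cfg)
}

# Closed vocabularies mirroring 450K manifest annotation.
FEATURE_LEVELS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body",
                    "3'UTR", "IGR")
CONTEXT_LEVELS <- c("Island", "Shore", "Shelf", "none")
CELLTYPE_NAMES <- c("CD8T", "CD4T", "Bcell", "NK", "Mono", "Gran")

#' Generate a 450K-style probe annotation table
#'
#' Probes are laid out in CpG-island-like runs: within-cluster spacing is at
#' most 500 bp, clusters on the same chromosome are at least 5 kb apart.
#' A configurable fraction of clusters is placed on sex chromosomes, and a
#' configurable fraction of probes is flagged non-CG, ambiguously mapping,
#' or as carrying a SNP at the probed CG — the categories removed by
#' [filter_probes()].
#'
#' @param config A [cohort_config()] object.
#' @return A `data.frame` with columns `probe_id`, `chrom`, `pos`
#'   (1-based, hg19-like), `gene`, `feature`, `cpg_context`, `is_noncg`,
#'   `is_ambiguous`, `has_snp_at_cg`, and `cluster_id`.
#' @export
generate_annotation <- function(config) {
  validate_cohort_config(config)
  m <- config$n_probes
  empty <- data.frame(probe_id = character(), chrom = character(),
                      pos = integer(), gene = character(),
                      feature = character(), cpg_context = character(),
                      is_noncg = logical(), is_ambiguous = logical(),
                      has_snp_at_cg = logical(), cluster_id = integer(),
                      stringsAsFactors = FALSE)
  if (m == 0L) return(empty)
  set.seed(derive_seed(config$seed, 11L))

  k <- config$island_cluster_size
  n_clusters <- ceiling(m / k)
  cluster_sizes <- rep(k, n_clusters)
  cluster_sizes[n_clusters] <- m - k * (n_clusters - 1L)

  n_sex_clusters <- round(config$frac_sex * n_clusters)
  sex_clusters <- if (n_sex_clusters > 0)
    sample.int(n_clusters, n_sex_clusters) else integer()
  autosomes <- paste0("chr", 1:22)
  chrom <- character(n_clusters)
  chrom[] <- sample(autosomes, n_clusters, replace = TRUE)
  if (n_sex_clusters > 0)
    chrom[sex_clusters] <- sample(c("chrX", "chrY"), n_sex_clusters,
                                  replace = TRUE)

  # Per chromosome, walk along the coordinate axis: >= 5 kb between
  # clusters, <= 500 bp between neighboring probes of a cluster.
  pos <- integer(m)
  cluster_id <- rep(seq_len(n_clusters), cluster_sizes)
  probe_ix <- split(seq_len(m), cluster_id)
  for (ch in unique(chrom)) {
    cl_on_ch <- which(chrom == ch)
    cursor <- 1e5
    for (cl in cl_on_ch) {
      cursor <- cursor + 5000 + round(stats::rexp(1, rate = 1 / 20000))
      sz <- cluster_sizes[cl]
      gaps <- if (sz > 1) sample(20:500, sz - 1L, replace = TRUE) else integer()
      pos[probe_ix[[cl]]] <- cursor + c(0L, cumsum(gaps))
      cursor <- pos[probe_ix[[cl]]][sz]
    }
  }

  # Context: full-size clusters are islands; short runs are shores/shelves.
  ctx_by_cluster <- ifelse(cluster_sizes >= 3, "Island",
                           ifelse(cluster_sizes == 2, "Shore",
                                  sample(c("Shelf", "none"), n_clusters,
                                         replace = TRUE)))
  feature_by_cluster <- sample(FEATURE_LEVELS, n_clusters, replace = TRUE,
                               prob = c(0.1, 0.1, 0.08, 0.06, 0.3, 0.06, 0.3))
  gene_by_cluster <- ifelse(feature_by_cluster == "IGR", "-",
                            sprintf("GENE%05d", seq_len(n_clusters)))

  ann <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(m)),
    chrom = chrom[cluster_id],
    pos = as.integer(pos),
    gene = gene_by_cluster[cluster_id],
    feature = feature_by_cluster[cluster_id],
    cpg_context = ctx_by_cluster[cluster_id],
    is_noncg = stats::runif(m) < config$frac_noncg,
    is_ambiguous = stats::runif(m) < config$frac_ambiguous,
    has_snp_at_cg = stats::runif(m) < config$frac_snp,
    cluster_id = cluster_id,
    stringsAsFactors = FALSE)
  rownames(ann) <- ann$probe_id
  ann
}

#' Generate purified-leukocyte reference methylation profiles
#'
#' Reference beta values are bimodal (mostly unmethylated or mostly
#' methylated), shared across cell types except on a designated
#' "discriminating" subset where cell types split into high/low methylation
#' states at least 0.3 apart, making the mixture identifiable for
#' deconvolution.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config A [cohort_config()] object.
#' @param min_spread Minimum between-cell-type beta spread on
#'   discriminating probes.
#' @return A list of class `cell_reference` with elements `profiles`
#'   (probes x cell types matrix), `discriminating` (probe IDs), and
#'   `celltypes`.
#' @export
generate_cell_reference <- function(annotation, config, min_spread = 0.3) {
  assert_that(nrow(annotation) > 0L, "annotation must be nonempty")
  set.seed(derive_seed(config$seed, 23L))
  m <- nrow(annotation)
  K <- config$n_celltypes
  celltypes <- if (K <= length(CELLTYPE_NAMES)) CELLTYPE_NAMES[seq_len(K)]
               else c(CELLTYPE_NAMES, paste0("CT", seq_len(K - 6L)))

  # Methylation state is coherent within a CpG cluster (islands are
  # jointly methylated or unmethylated); a minority of clusters sits at
  # intermediate methylation. Shared by all cell types off the
  # discriminating subset.
  cl <- annotation$cluster_id
  state_by_cluster <- sample(c("lo", "hi", "mid"), max(cl), replace = TRUE,
                             prob = c(0.4, 0.4, 0.2))
  state <- state_by_cluster[cl]
  base <- numeric(m)
  base[state == "lo"] <- stats::rbeta(sum(state == "lo"), 8, 40)
  base[state == "hi"] <- stats::rbeta(sum(state == "hi"), 40, 8)
  base[state == "mid"] <- stats::rbeta(sum(state == "mid"), 16, 16)
  profiles <- matrix(base, nrow = m, ncol = K,
                     dimnames = list(annotation$probe_id, celltypes))

  n_disc <- min(config$n_discriminating, m)
  disc <- sort(sample.int(m, n_disc))
  if (K > 1L) {
    for (i in disc) {
      # split cell types into a low and a high methylation state
      n_hi <- sample.int(K - 1L, 1L)
      hi_types <- sample.int(K, n_hi)
      lo_val <- stats::runif(1, 0.02, 0.25)
      hi_val <- lo_val + min_spread + stats::runif(1, 0, 0.95 - min_spread - lo_val)
      profiles[i, ] <- lo_val
      profiles[i, hi_types] <- hi_val
    }
  }
  structure(list(profiles = profiles,
                 discriminating = annotation$probe_id[disc],
                 celltypes = celltypes),
            class = "cell_reference")
}

# Blood-like Dirichlet concentration; granulocytes dominate whole blood.
default_dirichlet_alpha <- function(celltypes) {
  known <- c(CD8T = 6, CD4T = 12, Bcell = 4, NK = 4, Mono = 6, Gran = 40)
  a <- known[celltypes]
  a[is.na(a)] <- 5
  names(a) <- celltypes
  a
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  sw <- x / rowSums(x)
  colnames(sw) <- names(alpha)
  sw
}

#' Generate a synthetic donor cohort with known ground truth
#'
#' Each sample's beta profile is a cell-mixture-weighted combination of the
#' reference profiles, plus a planted group effect on planted probes (severe
#' samples only), a linear age trend and a sex offset on designated probes,
#' per-batch location shifts, and additive Gaussian noise, clipped to
#' (0, 1). QC tables (detection p-values, bead counts) carry a small planted
#' fraction of failures.
#'
#' @param config A [cohort_config()] object.
#' @param reference Output of [generate_cell_reference()]; generated from
#'   `config` when `NULL`.
#' @param annotation Output of [generate_annotation()]; generated from
#'   `config` when `NULL`.
#' @return A list of class `synthetic_cohort` with elements `beta`
#'   (probes x samples), `sample_sheet`, `qc` (list with `detection_p`,
#'   `bead_count`), `annotation`, `reference`, and `truth` (planted DMP
#'   effects, true cell proportions, batch shifts, group labels).
#' @export
generate_cohort <- function(config, reference = NULL, annotation = NULL) {
  validate_cohort_config(config)
  if (is.null(annotation)) annotation <- generate_annotation(config)
  if (is.null(reference)) reference <- generate_cell_reference(annotation, config)
  assert_that(nrow(annotation) == nrow(reference$profiles),
              "annotation and reference are inconsistent")
  set.seed(derive_seed(config$seed, 37L))

  n <- config$n_samples
  m <- config$n_probes
  sample_ids <- sprintf("D%03d", seq_len(n))
  group <- rep("no_mild", n)
  group[sample.int(n, config$n_severe)] <- "severe"
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]))
  batch <- paste0("slide", 1L + (sample.int(n, n) %% config$n_batches))
  # guarantee >= 2 samples per batch for the adjustment stage
  tb <- table(factor(batch, levels = paste0("slide", seq_len(config$n_batches))))
  if (any(tb < 2L) && n >= 2L * config$n_batches) {
    batch <- paste0("slide", rep_len(seq_len(config$n_batches), n))
  }

  # mixture weights; optional group shift to confound composition with group
  alpha <- default_dirichlet_alpha(reference$celltypes)
  W <- rdirichlet(n, alpha)
  if (config$confound_cells_with_group && config$n_celltypes >= 2L) {
    alpha_sev <- alpha
    alpha_sev[1] <- alpha_sev[1] * 2.5   # e.g. CD8T expansion in severe
    W[group == "severe", ] <- rdirichlet(sum(group == "severe"), alpha_sev)
  }
  rownames(W) <- sample_ids

  flagged <- annotation$is_noncg | annotation$is_ambiguous |
    annotation$has_snp_at_cg | annotation$chrom %in% c("chrX", "chrY")

  # candidate probes for planted effects: clean, mid-range, not
  # cell-type-discriminating (so mixture variation does not mask them)
  base_beta <- reference$profiles[, 1]
  is_disc <- annotation$probe_id %in% reference$discriminating
  candidate <- which(!flagged & !is_disc & base_beta > 0.25 & base_beta < 0.75)

  special <- integer()  # probes already assigned a designated role
  planted_ix <- integer()
  planted_delta <- numeric()
  if (config$n_planted_dmps > 0L) {
    if (config$n_cluster_dmps > 0L) {
      cl_ok <- vapply(split(seq_len(m), annotation$cluster_id), function(ix) {
        length(ix) >= config$n_cluster_dmps && all(ix %in% candidate)
      }, logical(1))
      assert_that(any(cl_ok),
                  "no island cluster is fully clean/mid-range for planting")
      cl <- as.integer(sample(names(cl_ok)[cl_ok], 1L))
      run <- which(annotation$cluster_id == cl)[seq_len(config$n_cluster_dmps)]
      planted_ix <- run
      # a coherent hypomethylated region, like the chr14q24.2-style DMR
      planted_delta <- -stats::runif(length(run),
                                     max(config$delta_beta_range[1], 0.12),
                                     config$delta_beta_range[2])
    }
    n_rest <- config$n_planted_dmps - length(planted_ix)
    pool <- setdiff(candidate, planted_ix)
    assert_that(length(pool) >= n_rest, "not enough clean probes to plant DMPs")
    rest <- sample(pool, n_rest)
    mag <- stats::runif(n_rest, config$delta_beta_range[1],
                        config$delta_beta_range[2])
    sgn <- sample(c(-1, 1), n_rest, replace = TRUE)
    # keep severe-group means inside (0, 1)
    sgn[base_beta[rest] + sgn * mag > 0.95] <- -1
    sgn[base_beta[rest] + sgn * mag < 0.05] <- 1
    planted_ix <- c(planted_ix, rest)
    planted_delta <- c(planted_delta, sgn * mag)
  }
  if (any(flagged[planted_ix]))
    stopf("planted probes overlap probes flagged for removal")
  special <- planted_ix

  pick_special <- function(k) {
    pool <- setdiff(setdiff(candidate, special), which(is_disc))
    out <- sample(pool, min(k, length(pool)))
    special <<- c(special, out)
    out
  }
  age_ix <- if (config$age_effect_probes > 0L)
    pick_special(config$age_effect_probes) else integer()
  sex_ix <- if (config$sex_effect_probes > 0L)
    pick_special(config$sex_effect_probes) else integer()

  # assemble the signal: mixture + planted + age + sex + batch + noise
  beta <- reference$profiles %*% t(W)
  if (length(planted_ix))
    beta[planted_ix, group == "severe"] <-
      beta[planted_ix, group == "severe"] + planted_delta
  if (length(age_ix))
    beta[age_ix, ] <- beta[age_ix, ] +
      config$age_slope * matrix(age - mean(age), nrow = length(age_ix),
                                ncol = n, byrow = TRUE)
  if (length(sex_ix))
    beta[sex_ix, sex == "M"] <- beta[sex_ix, sex == "M"] + config$sex_offset

  batch_levels <- sort(unique(batch))
  gamma <- matrix(stats::rnorm(length(batch_levels) * m, 0,
                               config$batch_shift_sd),
                  nrow = length(batch_levels),
                  dimnames = list(batch_levels, annotation$probe_id))
  scale_b <- exp(stats::rnorm(length(batch_levels), 0, config$batch_scale_sd))
  names(scale_b) <- batch_levels
  if (length(batch_levels) > 1L) {
    for (b in batch_levels) {
      cols <- batch == b
      beta[, cols] <- beta[, cols] + gamma[b, ] +
        matrix(stats::rnorm(m * sum(cols), 0, config$noise_sd * scale_b[b]),
               nrow = m)
    }
  } else {
    beta <- beta + matrix(stats::rnorm(m * n, 0, config$noise_sd), nrow = m)
  }
  beta <- clip_beta(beta)
  dimnames(beta) <- list(annotation$probe_id, sample_ids)

  # QC tables with a small planted failure fraction
  detection_p <- matrix(stats::runif(m * n, 0, 0.005), nrow = m,
                        dimnames = dimnames(beta))
  bead_count <- matrix(5L + stats::rpois(m * n, 15), nrow = m,
                       dimnames = dimnames(beta))
  n_fail <- round(config$qc_fail_frac * m)
  qc_pool <- setdiff(seq_len(m), special)
  fail_det <- if (n_fail > 0) sample(qc_pool, n_fail) else integer()
  fail_bead <- if (n_fail > 0) sample(setdiff(qc_pool, fail_det), n_fail)
               else integer()
  for (i in fail_det)
    detection_p[i, sample.int(n, max(1L, n %/% 3))] <- stats::runif(1, 0.05, 0.9)
  for (i in fail_bead)
    bead_count[i, sample.int(n, max(1L, ceiling(0.10 * n)))] <-
      sample(0:2, 1L)

  sample_sheet <- data.frame(sample_id = sample_ids, group = group,
                             sex = sex, age_years = age, batch_id = batch,
                             stringsAsFactors = FALSE)
  truth <- list(
    planted_dmp_delta = stats::setNames(planted_delta,
                                        annotation$probe_id[planted_ix]),
    cluster_dmp_ids = annotation$probe_id[
      planted_ix[seq_len(config$n_cluster_dmps)]],
    age_probe_ids = annotation$probe_id[age_ix],
    sex_probe_ids = annotation$probe_id[sex_ix],
    true_cell_proportions = W,
    true_batch_shifts = gamma,
    true_batch_scales = scale_b,
    true_group_labels = stats::setNames(as.integer(group == "severe"),
                                        sample_ids))
  stopifnot(max(abs(rowSums(W) - 1)) < 1e-12)
  structure(list(beta = beta, sample_sheet = sample_sheet,
                 qc = list(detection_p = detection_p, bead_count = bead_count),
                 annotation = annotation, reference = reference,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}
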