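# Shared fixture builders; everything is generated in code at test time.

# A small cohort with strong planted signal, used where the focus is the
# downstream machinery rather than power.
small_cohort <- function(seed = 101, n_probes = 1500,
                         n_planted_dmps = 10L, n_cluster_dmps = 0L,
                         n_discriminating = 200L, ...) {
  cfg <- cohort_config(n_probes = n_probes,
                       n_planted_dmps = n_planted_dmps,
                       n_cluster_dmps = n_cluster_dmps,
                       age_effect_probes = 10L, sex_effect_probes = 10L,
                       n_discriminating = n_discriminating,
                       seed = seed, ...)
  generate_cohort(cfg)
}

# A pure-noise cohort: no planted effects, one batch, no age/sex trends.
null_cohort <- function(seed, n_probes = 1000, ...) {
  cfg <- cohort_config(n_probes = n_probes, n_planted_dmps = 0L,
                       n_cluster_dmps = 0L, n_batches = 1L,
                       age_effect_probes = 0L, sex_effect_probes = 0L,
                       n_discriminating = 200L, seed = seed, ...)
  generate_cohort(cfg)
}

# Hand-built beta matrix with dimnames.
toy_beta <- function(values, n_probes, n_samples) {
  matrix(values, n_probes, n_samples,
         dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

# Minimal all-passing QC tables for a beta matrix.
passing_qc <- function(beta) {
  list(detection_p = matrix(1e-5, nrow(beta), ncol(beta),
                            dimnames = dimnames(beta)),
       bead_count = matrix(10L, nrow(beta), ncol(beta),
                           dimnames = dimnames(beta)))
}

# Minimal clean annotation for hand-built probes.
toy_annotation <- function(probe_ids, chrom = "chr1",
                           pos = seq(1e5, by = 10000,
                                     length.out = length(probe_ids))) {
  if (length(probe_ids) == 0L) {
    return(data.frame(probe_id = character(), chrom = character(),
                      pos = integer(), gene = character(),
                      feature = character(), cpg_context = character(),
                      is_noncg = logical(), is_ambiguous = logical(),
                      has_snp_at_cg = logical(), cluster_id = integer(),
                      stringsAsFactors = FALSE))
  }
  ann <- data.frame(probe_id = probe_ids,
                    chrom = rep_len(chrom, length(probe_ids)), pos = pos,
                    gene = "-", feature = "Body", cpg_context = "none",
                    is_noncg = FALSE, is_ambiguous = FALSE,
                    has_snp_at_cg = FALSE,
                    cluster_id = seq_along(probe_ids),
                    stringsAsFactors = FALSE)
  rownames(ann) <- probe_ids
  ann
}
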