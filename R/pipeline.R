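# End-to-end orchestration: the discovery arm (filter -> batch adjust ->
# cell estimation -> DMP -> DMR -> nested LOOCV -> recurrence-ranked
# table) and the replication arm (standard curve -> PMR -> group test ->
# ROC threshold).

#' Run configuration for the pipeline
#'
#' @param alpha Bonferroni family-wise level for DMP selection.
#' @param min_abs_delta Minimum absolute delta-beta for DMP selection.
#' @param nsc_delta Shrinkage threshold of the centroid classifier.
#' @param dmr Parameters from [dmr_params()].
#' @param detection_rule Probe-filter detection-p reading, see
#'   [filter_probes()].
#' @param preserve Covariates protected by batch adjustment.
#' @param run_dmr,run_loocv Stage toggles.
#' @param dilution_factor Fold dilution of the MethyLight standard series.
#' @param seed Seed recorded in reports (generation happens upstream).
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, min_abs_delta = 0.05, nsc_delta = 1,
                       dmr = dmr_params(), detection_rule = "any",
                       preserve = "group", run_dmr = TRUE,
                       run_loocv = TRUE, dilution_factor = 4, seed = 1L) {
  structure(list(alpha = alpha, min_abs_delta = min_abs_delta,
                 nsc_delta = nsc_delta, dmr = dmr,
                 detection_rule = detection_rule, preserve = preserve,
                 run_dmr = run_dmr, run_loocv = run_loocv,
                 dilution_factor = dilution_factor, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the discovery arm of the pipeline
#'
#' Executes probe filtering, empirical-Bayes batch adjustment, leukocyte
#' deconvolution, covariate-adjusted DMP analysis, DMR calling, nested
#' leave-one-out cross-validation, and recurrence ranking. Any stage
#' failure propagates with the failing stage named.
#'
#' @param beta Raw beta matrix (probes x samples).
#' @param sample_sheet Sample sheet (`sample_id`, `group`, `sex`,
#'   `age_years`, `batch_id`).
#' @param annotation Probe annotation table.
#' @param qc List with `detection_p` and `bead_count` matrices.
#' @param reference Cell-type reference (a `cell_reference` or matrix);
#'   `NULL` skips deconvolution (no cell covariates in the model).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, report files (filtered
#'   beta TSV, DMP/DMR TSVs, LOOCV JSON, ranked table) are written there.
#' @return A list of class `discovery_report` with elements
#'   `filter_report`, `batch_model`, `cell_proportions`, `dmps`, `dmrs`,
#'   `loocv`, `ranked_dmps`, `config`, and `n` bookkeeping.
#' @export
run_discovery <- function(beta, sample_sheet, annotation, qc,
                          reference = NULL, config = run_config(),
                          out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  filt <- stage("filter", filter_probes(beta, annotation, qc,
                                        detection_rule = config$detection_rule))
  beta_f <- filt$beta

  adj <- stage("batch_adjust",
               combat_adjust(beta_f, sample_sheet,
                             preserve = config$preserve))
  beta_a <- adj$beta

  props <- NULL
  sheet <- sample_sheet
  if (!is.null(reference)) {
    props <- stage("cell_composition",
                   estimate_cell_proportions(beta_a, reference))
    sheet <- add_cell_proportions(sample_sheet, props)
  }

  dmp_res <- stage("dmp", run_dmp_analysis(
    beta_a, sheet, alpha = config$alpha,
    min_abs_delta = config$min_abs_delta,
    annotation = annotation))

  dmrs <- NULL
  if (isTRUE(config$run_dmr)) {
    dmrs <- stage("dmr", {
      ann_f <- annotation[rownames(beta_a), , drop = FALSE]
      radii <- compute_lasso_radii(ann_f, config$dmr)
      stats_df <- data.frame(probe_id = rownames(beta_a),
                             chrom = ann_f$chrom, pos = ann_f$pos,
                             p = unname(dmp_res$stats$p),
                             stringsAsFactors = FALSE)
      stats_df <- stats_df[order(stats_df$chrom, stats_df$pos), ]
      call_dmrs(stats_df, radii, config$dmr)
    })
  }

  loocv <- NULL
  ranked <- NULL
  if (isTRUE(config$run_loocv)) {
    loocv <- stage("loocv", loocv_evaluate(
      beta_a, sheet, alpha = config$alpha,
      min_abs_delta = config$min_abs_delta, delta = config$nsc_delta))
    ranked <- stage("rank", rank_dmp_recurrence(loocv, dmp_res$dmps))
  }

  report <- structure(list(
    filter_report = filt$report, batch_model = adj$model,
    cell_proportions = props, dmps = dmp_res$dmps, dmrs = dmrs,
    loocv = loocv, ranked_dmps = ranked, config = config,
    n = list(samples = ncol(beta), probes_input = nrow(beta),
             probes_surviving = nrow(beta_a))), class = "discovery_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_beta_tsv(beta_a, file.path(out_dir, "beta_filtered_adjusted.tsv"))
    utils::write.table(dmp_res$dmps, file.path(out_dir, "dmps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dmrs)) {
      utils::write.table(dmrs, file.path(out_dir, "dmrs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    }
    if (!is.null(loocv)) {
      jsonlite::write_json(
        list(auc = loocv$auc, auc_ci = loocv$auc_ci,
             mean_training_auc = loocv$mean_training_auc,
             zero_dmp_iterations = loocv$zero_dmp_iterations,
             predictions = loocv$predictions),
        file.path(out_dir, "loocv.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(loocv$roc, file.path(out_dir, "roc_points.csv"),
                       row.names = FALSE)
      utils::write.table(ranked, file.path(out_dir, "dmps_ranked.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(config = unclass(config)[setdiff(names(config), "dmr")],
           dmr_params = unclass(config$dmr),
           filter = report$filter_report[c("n_input", "n_removed",
                                           "n_surviving",
                                           "removed_by_rule")],
           n = report$n),
      file.path(out_dir, "discovery_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Run the MethyLight replication arm
#'
#' Standard-curve fitting, PMR quantification, two-sided Wilcoxon rank-sum
#' comparison of severe vs no/mild donors, and the ROC threshold closest
#' to the top-left corner.
#'
#' @param wells Plate wells `data.frame` (see [quantify_plate()]).
#' @param config A [run_config()].
#' @param out_dir Optional output directory for PMR CSV and threshold JSON.
#' @return A list of class `replication_report`: `pmr`, `curves`,
#'   `control_pmr`, `excluded`, `wilcoxon`, `threshold`.
#' @export
run_replication <- function(wells, config = run_config(), out_dir = NULL) {
  quant <- quantify_plate(wells, dilution_factor = config$dilution_factor)
  pmr <- quant$pmr
  usable <- !(pmr$sample_id %in% quant$excluded) & !is.na(pmr$group)
  sev <- pmr$pmr[usable & pmr$group == "severe"]
  rest <- pmr$pmr[usable & pmr$group != "severe"]
  if (!length(sev) || !length(rest))
    stopf("stage 'group_test' failed: need both groups with defined PMR")
  wil <- wilcoxon_rank_sum(sev, rest)
  thr <- closest_topleft_threshold(pmr$pmr[usable],
                                   pmr$group[usable] == "severe")
  report <- structure(list(pmr = pmr, curves = quant$curves,
                           control_pmr = quant$control_pmr,
                           excluded = quant$excluded, wilcoxon = wil,
                           threshold = thr, config = config),
                      class = "replication_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pmr, file.path(out_dir, "pmr.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(wilcoxon_p = wil$p, wilcoxon_U = wil$U,
           threshold = thr, control_pmr = quant$control_pmr,
           excluded = quant$excluded,
           curves = lapply(quant$curves, unclass)),
      file.path(out_dir, "replication_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}
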