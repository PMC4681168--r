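# Plain-text readers/writers for the pipeline's exchange formats. All
# tables are TSV/CSV with '.' decimal separators; coordinates stay 1-based.

#' Write / read a beta matrix as TSV
#'
#' Probe rows, sample columns, first column `probe_id`.
#'
#' @param beta Beta matrix.
#' @param path File path.
#' @return `path` invisibly / the beta matrix.
#' @export
write_beta_tsv <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Write / read a sample sheet as CSV
#' @param sheet Sample sheet `data.frame`.
#' @param path File path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a probe annotation table as TSV
#' @param annot Annotation `data.frame`.
#' @param path File path.
#' @export
write_annotation_tsv <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(ann) <- ann$probe_id
  ann
}

#' Write / read a MethyLight plate as CSV
#' @param wells Plate wells `data.frame`.
#' @param path File path.
#' @export
write_plate_csv <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Persist a whole synthetic cohort to a directory
#'
#' Writes the beta TSV, sample sheet CSV, annotation TSV, QC TSVs and the
#' ground truth JSON, the formats the discovery pipeline reads back.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_sample_sheet(cohort$sample_sheet, file.path(dir, "sample_sheet.csv"))
  write_annotation_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_beta_tsv(cohort$qc$detection_p, file.path(dir, "detection_p.tsv"))
  write_beta_tsv(cohort$qc$bead_count, file.path(dir, "bead_count.tsv"))
  truth <- cohort$truth
  truth$true_cell_proportions <- as.data.frame(truth$true_cell_proportions)
  truth$true_batch_shifts <- NULL  # large; regenerate from config if needed
  # named vectors serialize as bare arrays; keep the names via lists
  for (nm in c("planted_dmp_delta", "true_batch_scales",
               "true_group_labels"))
    truth[[nm]] <- as.list(truth[[nm]])
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A list with `beta`, `sample_sheet`, `annotation`, `qc`.
#' @export
read_cohort <- function(dir) {
  list(beta = read_beta_tsv(file.path(dir, "beta.tsv")),
       sample_sheet = read_sample_sheet(file.path(dir, "sample_sheet.csv")),
       annotation = read_annotation_tsv(file.path(dir, "annotation.tsv")),
       qc = list(
         detection_p = read_beta_tsv(file.path(dir, "detection_p.tsv")),
         bead_count = read_beta_tsv(file.path(dir, "bead_count.tsv"))))
}
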