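# End-to-end orchestration: nomenclature overlap -> platform-specific
# processing -> QC -> cross-platform correlation -> differential analysis,
# with a deterministic on-disk report bundle.

.sorted_rows <- function(df) {
  keys <- intersect(c("lipid_class", "annotation", "lipid", "lipid_name",
                      "analyte", "standard_id"), names(df))
  if (length(keys)) df <- df[do.call(order, df[keys]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Run the full cross-platform pipeline on a study
#'
#' Executes every stage on a (typically synthetic) paired-platform study:
#' name conversion and coverage overlap, untargeted feature-table processing
#' (blank removal, two-IS normalization, presence filter, imputation, adduct
#' collapse), targeted MRM quantification against the IS panel, QC metrics
#' (precision, calibration, accuracy, with and without dropping the top
#' calibration point), per-lipid cross-platform correlation and dilution
#' correlation, and per-platform differential analysis with class totals and
#' the cross-platform consensus of deregulated lipids.
#'
#' A report bundle of CSV files plus `run_log.txt` is written to `outDir`
#' with fixed row ordering and fixed 6-significant-digit float formatting,
#' so identical inputs give byte-identical reports.
#'
#' @param study a `"SyntheticStudy"` from [generateStudy()], or a list with
#'   the same elements assembled from real data files.
#' @param outDir output directory (created if needed).
#' @param fdr significance threshold for the differential stage.
#' @param excludeClasses classes excluded from cross-platform correlation
#'   and consensus (default TAG, whose reporting levels differ).
#' @param blankRatio,presenceFraction untargeted processing thresholds.
#' @return Invisibly, a list with all stage results (`overlap`,
#'   `normalizedA`, `concentrationsB`, `qc`, `qcDropHighest`, `pairs`,
#'   `correlation`, `dilution`, `variability`, `differentialA`,
#'   `differentialB`, `classTotalsA`, `classTotalsB`, `consensus`, `files`).
#' @export
runPipeline <- function(study, outDir, fdr = 0.05, excludeClasses = "TAG",
                        blankRatio = 0.5, presenceFraction = 0.5) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## nomenclature: identification lists -> target-level overlap
  rdA <- SummarizedExperiment::rowData(study$platformA)
  endo <- !(rownames(study$platformA) %in% study$isFeatures) &
    !is.na(rdA$lipid_name)
  names_a <- unique(as.character(rdA$lipid_name[endo]))
  names_b <- sort(setdiff(unique(study$scansB$lipid_name),
                          study$isPanel$lipid_name))
  ann_a <- convertNameSet(names_a)
  ann_b <- convertNameSet(names_b)
  overlap <- matchAnnotations(ann_a, ann_b)
  note("nomenclature: %d A names -> %d annotations; %d B names -> %d annotations",
       length(names_a), length(ann_a), length(names_b), length(ann_b))
  note("overlap: %d shared, %d A-only, %d B-only (union %d)",
       overlap$venn[["shared"]], overlap$venn[["a_only"]],
       overlap$venn[["b_only"]], overlap$n_union)

  ## platform A processing
  normA <- processLcms(study$platformA, study$isFeatures,
                       blankRatio = blankRatio,
                       minFraction = presenceFraction)
  rd <- SummarizedExperiment::rowData(normA)
  conv <- lapply(as.character(rd$lipid_name), convertToTargetLevel)
  rd$lipid_class <- vapply(conv, function(s) lipidClass(s)[1L], character(1))
  rd$canonical <- vapply(conv, function(s)
    if (length(s) == 1L) canonicalText(s) else NA_character_, character(1))
  SummarizedExperiment::rowData(normA) <- rd
  plog <- processingLog(normA)
  for (i in seq_len(nrow(plog)))
    note("lcms %s: %d -> %d rows %s", plog$stage[i], plog$rows_in[i],
         plog$rows_out[i], plog$note[i])

  ## platform B quantification
  concB <- quantifyStudy(study$scansB, study$isPanel, groups = study$groups)
  note("targeted quantification: %d lipids x %d samples",
       nrow(concB), ncol(concB))

  ## QC metrics
  qc <- qcSummary(study$replicates, study$calibrationB, dropHighest = FALSE)
  qc_drop <- qcSummary(study$replicates, study$calibrationB,
                       dropHighest = TRUE)
  note("qc: median intra-day CV %.2f%%, inter-day CV %.2f%%",
       qc$medians[["median_intraday_cv_pct"]],
       qc$medians[["median_interday_cv_pct"]])

  ## cross-platform agreement
  pairs <- buildMatchedPairs(normA, concB, overlap,
                             excludeClasses = excludeClasses)
  corr <- perLipidCorrelation(pairs)
  dil <- dilutionCorrelation(study$dilutionA, study$calibrationB)
  vari <- tryCatch(correlationVsVariability(pairs, corr),
                   lipidbridgeError = function(e) NULL)
  note("correlation: %d matched pairs, median r %.3f; dilution median r %.3f",
       nrow(pairs$annotation), corr$median_r, dil$median_r)

  ## differential analysis
  groupsA <- as.character(SummarizedExperiment::colData(normA)$group)
  diffA <- differentialAnalysis(normA, groupsA, fdr = fdr)
  diffB <- differentialAnalysis(concB, study$groups[colnames(concB)],
                                fdr = fdr)
  ctA <- classTotalsTest(normA, groups = groupsA)
  ctB <- classTotalsTest(concB, groups = study$groups[colnames(concB)])
  consensus <- crossPlatformConsensus(diffA, diffB,
                                      excludeClasses = excludeClasses)
  note("differential: %d/%d significant (A), %d/%d (B); consensus %d shared same-direction",
       sum(diffA$significant), nrow(diffA), sum(diffB$significant),
       nrow(diffB), consensus$venn[["shared"]])

  ## report bundle
  files <- c(
    overlap = "overlap.csv", per_class = "overlap_per_class.csv",
    qc_analytes = "qc_analytes.csv", qc_calibration = "qc_calibration.csv",
    qc_medians = "qc_medians.csv",
    correlation = "correlation_per_lipid.csv",
    correlation_class = "correlation_by_class.csv",
    dilution = "dilution_correlation.csv",
    diff_a = "differential_lcms.csv", diff_b = "differential_targeted.csv",
    totals_a = "class_totals_lcms.csv", totals_b = "class_totals_targeted.csv",
    consensus = "consensus.csv")
  paths <- stats::setNames(file.path(outDir, files), names(files))

  writeOverlapReport(overlap, paths[["overlap"]])
  .write_report_csv(.sorted_rows(overlap$per_class), paths[["per_class"]])
  .write_report_csv(.sorted_rows(qc$analytes), paths[["qc_analytes"]])
  cal_both <- merge(qc$calibration, qc_drop$calibration,
                    by = "standard_id", suffixes = c("", "_drop_highest"))
  .write_report_csv(.sorted_rows(cal_both), paths[["qc_calibration"]])
  med <- rbind(
    data.frame(metric = names(qc$medians), value = unname(qc$medians)),
    data.frame(metric = paste0(names(qc_drop$medians), "_drop_highest"),
               value = unname(qc_drop$medians)),
    data.frame(metric = c("median_cross_platform_r", "median_dilution_r"),
               value = c(corr$median_r, dil$median_r)))
  .write_report_csv(med, paths[["qc_medians"]])
  .write_report_csv(.sorted_rows(corr$per_lipid), paths[["correlation"]])
  .write_report_csv(.sorted_rows(corr$by_class), paths[["correlation_class"]])
  .write_report_csv(.sorted_rows(dil$per_standard), paths[["dilution"]])
  .write_report_csv(.sorted_rows(diffA), paths[["diff_a"]])
  .write_report_csv(.sorted_rows(diffB), paths[["diff_b"]])
  .write_report_csv(.sorted_rows(ctA), paths[["totals_a"]])
  .write_report_csv(.sorted_rows(ctB), paths[["totals_b"]])
  .write_report_csv(.sorted_rows(consensus$shared_same_direction),
                    paths[["consensus"]])
  writeLines(log_lines, file.path(outDir, "run_log.txt"))

  invisible(list(
    overlap = overlap, normalizedA = normA, concentrationsB = concB,
    qc = qc, qcDropHighest = qc_drop, pairs = pairs, correlation = corr,
    dilution = dil, variability = vari, differentialA = diffA,
    differentialB = diffB, classTotalsA = ctA, classTotalsB = ctB,
    consensus = consensus,
    files = c(paths, run_log = file.path(outDir, "run_log.txt"))))
}
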