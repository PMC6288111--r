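# Untargeted LC-MS feature-table processing: blank-feature removal,
# two-IS ratio normalization, presence filtering, minimum imputation and
# primary-adduct selection. The fixed pipeline order is
# blank -> normalize -> presence -> impute -> adduct (see processLcms).

# mean intensity treating missing as zero (undetected carries no signal)
.mean0 <- function(m) {
  m[is.na(m)] <- 0
  rowMeans(m)
}

#' Remove features dominated by solvent blanks
#'
#' Drops features whose mean intensity across blank samples exceeds
#' `blankRatio` times their mean intensity across biological samples
#' (missing values count as zero signal). Features absent from blanks are
#' always retained.
#'
#' @param x a [LipidomicsExperiment-class] with a `role` column in `colData`.
#' @param blankRatio blank-to-biological mean intensity ratio above which a
#'   feature is considered background (default 0.5).
#' @param protect row identifiers never dropped regardless of their blank
#'   signal -- the spiked IS features, which are present in solvent blanks
#'   by construction.
#' @return The filtered table; the number of dropped features is appended to
#'   the processing log. If the table has no blank samples the input is
#'   returned unchanged with a warning.
#' @export
removeBlankFeatures <- function(x, blankRatio = 0.5, protect = character(0)) {
  stopifnot(is(x, "LipidomicsExperiment"), blankRatio >= 0)
  roles <- sampleRole(x)
  if (!any(roles == "blank")) {
    warning("no blank samples; blank-feature removal skipped")
    return(.append_log(x, "remove_blank", nrow(x), nrow(x), "no blanks"))
  }
  a <- abundance(x)
  blank_mean <- .mean0(a[, roles == "blank", drop = FALSE])
  bio_mean <- .mean0(a[, roles == "biological", drop = FALSE])
  drop <- blank_mean > blankRatio * bio_mean & blank_mean > 0
  drop[rownames(x) %in% protect] <- FALSE
  out <- x[!drop, ]
  .append_log(out, "remove_blank", nrow(x), nrow(out),
              sprintf("dropped %d blank-dominated features", sum(drop)))
}

#' Normalize by the ratio of two spiked internal standards
#'
#' Per-sample normalization factors are the mean, over the two spiked IS
#' features, of each IS intensity divided by that IS's mean across biological
#' samples; every intensity in a sample is divided by its factor. Factors
#' average to 1 across biological samples by construction. The output keeps
#' biological samples only (blanks and pools have served their purpose) and
#' drops the IS feature rows; factors are stored in
#' `metadata(x)$normalization_factors`.
#'
#' @param x a [LipidomicsExperiment-class] feature table.
#' @param isFeatures exactly two row identifiers (rownames) of the spiked IS
#'   features.
#' @return A normalized [LipidomicsExperiment-class] with units
#'   `"relative"`.
#' @export
normalizeBySpikedIS <- function(x, isFeatures) {
  stopifnot(is(x, "LipidomicsExperiment"))
  if (length(isFeatures) != 2L)
    .input_error("exactly two spiked IS features are required")
  if (!all(isFeatures %in% rownames(x)))
    .input_error(sprintf("IS feature(s) not found: %s",
                         paste(setdiff(isFeatures, rownames(x)),
                               collapse = ", ")))
  roles <- sampleRole(x)
  bio <- roles == "biological"
  a <- abundance(x)
  is_mat <- a[isFeatures, bio, drop = FALSE]
  bad <- colSums(is.na(is_mat) | is_mat <= 0) > 0
  if (any(bad))
    .input_error(sprintf("spiked IS missing or zero in sample(s): %s",
                         paste(colnames(is_mat)[bad], collapse = ", ")))
  ratios <- is_mat / rowMeans(is_mat)
  factors <- colMeans(ratios)

  norm <- sweep(a[, bio, drop = FALSE], 2L, factors, "/")
  keep <- !(rownames(x) %in% isFeatures)
  out <- LipidomicsExperiment(
    norm[keep, , drop = FALSE],
    rowData = SummarizedExperiment::rowData(x)[keep, , drop = FALSE],
    colData = SummarizedExperiment::colData(x)[bio, , drop = FALSE],
    units = "relative",
    platform = S4Vectors::metadata(x)$platform)
  S4Vectors::metadata(out)$normalization_factors <- factors
  S4Vectors::metadata(out)$processing_log <-
    S4Vectors::metadata(x)$processing_log
  .append_log(out, "normalize_is", nrow(x), nrow(out),
              sprintf("factors mean %.4f", mean(factors)))
}

#' Keep lipids present in more than a fraction of samples
#'
#' Presence means a non-missing, strictly positive intensity. The inequality
#' is strict: with `minFraction = 0.5`, a lipid detected in exactly half of
#' the biological samples is dropped.
#'
#' @param x a [LipidomicsExperiment-class].
#' @param minFraction fraction of biological samples that must exceed
#'   detection (default 0.5).
#' @return The filtered table.
#' @export
filterByPresence <- function(x, minFraction = 0.5) {
  stopifnot(is(x, "LipidomicsExperiment"),
            minFraction >= 0, minFraction <= 1)
  bio <- sampleRole(x) == "biological"
  a <- abundance(x)[, bio, drop = FALSE]
  present <- !is.na(a) & a > 0
  keep <- rowMeans(present) > minFraction
  out <- x[keep, ]
  .append_log(out, "presence_filter", nrow(x), nrow(out),
              sprintf("kept lipids present in > %d%% of samples",
                      round(100 * minFraction)))
}

#' Impute missing values by the per-lipid minimum
#'
#' Each missing (or zero, i.e. undetected) entry is replaced by that lipid's
#' minimum detected value across biological samples. Idempotent.
#'
#' @param x a [LipidomicsExperiment-class]; every row must have at least one
#'   detected value (guaranteed after [filterByPresence()]).
#' @return The imputed table with no missing values.
#' @export
imputeMinimum <- function(x) {
  stopifnot(is(x, "LipidomicsExperiment"))
  a <- abundance(x)
  bio <- sampleRole(x) == "biological"
  for (i in seq_len(nrow(a))) {
    row <- a[i, bio]
    obs <- row[!is.na(row) & row > 0]
    miss <- is.na(a[i, ]) | a[i, ] == 0
    if (!any(miss)) next
    if (length(obs) == 0L)
      .input_error(sprintf(
        "lipid '%s' has no detected value to impute from", rownames(a)[i]))
    a[i, miss] <- min(obs)
  }
  SummarizedExperiment::assay(x, "abundance") <- a
  .append_log(x, "impute_minimum", nrow(x), nrow(x), "")
}

#' Keep the most abundant adduct per lipid
#'
#' For lipids detected as several adduct features, retains the feature with
#' the highest mean intensity across biological samples; exact ties go to the
#' lexicographically first adduct label, so the choice is deterministic.
#' Features without an identified `lipid_name` pass through unchanged.
#'
#' @param x a [LipidomicsExperiment-class] whose `rowData` has `lipid_name`
#'   and `adduct` columns.
#' @return The collapsed table, one row per identified lipid.
#' @export
selectPrimaryAdduct <- function(x) {
  stopifnot(is(x, "LipidomicsExperiment"))
  rd <- SummarizedExperiment::rowData(x)
  if (!"lipid_name" %in% names(rd))
    .input_error("rowData must contain 'lipid_name'")
  adduct <- if ("adduct" %in% names(rd)) as.character(rd$adduct)
            else rep("", nrow(x))
  name <- as.character(rd$lipid_name)
  bio <- sampleRole(x) == "biological"
  mean_int <- .mean0(abundance(x)[, bio, drop = FALSE])

  keep <- rep(TRUE, nrow(x))
  identified <- !is.na(name) & nzchar(name)
  for (nm in unique(name[identified])) {
    idx <- which(identified & name == nm)
    if (length(idx) < 2L) next
    best <- idx[order(-mean_int[idx], adduct[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  out <- x[keep, ]
  .append_log(out, "adduct_collapse", nrow(x), nrow(out),
              sprintf("collapsed %d secondary adduct features", sum(!keep)))
}

#' Full untargeted feature-table processing
#'
#' Composes the five processing stages in their fixed order: blank-feature
#' removal, two-IS normalization, strict >50\% presence filtering, per-lipid
#' minimum imputation, and primary-adduct selection. Each stage is idempotent
#' and the composition is deterministic; per-stage row counts are recorded in
#' the processing log (see [processingLog()]).
#'
#' @param x a raw [LipidomicsExperiment-class] feature table with sample
#'   roles.
#' @param isFeatures the two spiked IS feature identifiers.
#' @param blankRatio see [removeBlankFeatures()].
#' @param minFraction see [filterByPresence()].
#' @return The normalized, filtered, imputed, adduct-collapsed table.
#' @export
processLcms <- function(x, isFeatures, blankRatio = 0.5, minFraction = 0.5) {
  x <- removeBlankFeatures(x, blankRatio, protect = isFeatures)
  x <- normalizeBySpikedIS(x, isFeatures)
  x <- filterByPresence(x, minFraction)
  x <- imputeMinimum(x)
  selectPrimaryAdduct(x)
}

#' Read an untargeted feature table from CSV
#'
#' @param featurePath CSV with columns `feature_id`, `mz`, `rt`, `adduct`,
#'   `lipid_name`, then one column per sample.
#' @param samplePath sample metadata CSV with columns `sample_id`, `role`
#'   and optionally `group`.
#' @return A [LipidomicsExperiment-class] with units `"intensity"`.
#' @export
readFeatureTable <- function(featurePath, samplePath) {
  feat <- utils::read.csv(featurePath, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta_cols <- c("feature_id", "mz", "rt", "adduct", "lipid_name")
  missing_cols <- setdiff(meta_cols, names(feat))
  if (length(missing_cols))
    .input_error(sprintf("feature table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  samples <- utils::read.csv(samplePath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(samples)))
    .input_error("sample metadata needs 'sample_id' and 'role' columns")
  if (!all(samples$sample_id %in% names(feat)))
    .input_error("sample metadata lists samples absent from the feature table")
  a <- as.matrix(feat[, samples$sample_id, drop = FALSE])
  rownames(a) <- feat$feature_id
  colnames(a) <- samples$sample_id
  LipidomicsExperiment(a, rowData = feat[, meta_cols],
                       colData = samples, units = "intensity",
                       platform = "untargeted LC-MS")
}
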