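# Quantitative cross-platform agreement: per-lipid Pearson correlation of
# relative abundances (platform A) against concentrations (platform B) on
# shared biological samples, dilution-ladder correlation per internal
# standard, and the association between biological variability and
# inter-platform correlation.

#' Build matched lipid pairs across platforms
#'
#' Pairs the two platforms' measurements for every annotation in the
#' cross-platform overlap, on the samples shared by both tables. Annotations
#' of excluded classes (by default TAG, whose nomenclature differs between
#' platforms) are left out. An annotation is paired only when it maps to
#' exactly one row in each table.
#'
#' @param tableA,tableB [LipidomicsExperiment-class] objects whose `rowData`
#'   carries a `canonical` column of target-level annotations.
#' @param overlap the shared annotation set: a [SpeciesAnnotations-class] or
#'   the result of [matchAnnotations()] (its `shared` element is used).
#' @param excludeClasses classes dropped before pairing (default `"TAG"`).
#' @return An object of class `"matchedLipidPairs"`: list with `annotation`
#'   (data.frame of annotation and class), `a` and `b` (aligned value
#'   matrices, lipids x shared samples) and `samples`.
#' @export
buildMatchedPairs <- function(tableA, tableB, overlap,
                              excludeClasses = "TAG") {
  if (inherits(overlap, "annotationOverlap")) overlap <- overlap$shared
  stopifnot(is(overlap, "SpeciesAnnotations"),
            is(tableA, "LipidomicsExperiment"),
            is(tableB, "LipidomicsExperiment"))
  samples <- intersect(colnames(tableA), colnames(tableB))
  if (length(samples) < 3L)
    .input_error("matched pairs need at least 3 shared samples")

  keep <- !lipidClass(overlap) %in% excludeClasses
  ann <- canonicalText(overlap)[keep]
  cls <- lipidClass(overlap)[keep]

  canA <- as.character(SummarizedExperiment::rowData(tableA)$canonical)
  canB <- as.character(SummarizedExperiment::rowData(tableB)$canonical)
  ok <- vapply(ann, function(a) {
    sum(canA == a, na.rm = TRUE) == 1L && sum(canB == a, na.rm = TRUE) == 1L
  }, logical(1))
  ann <- ann[ok]; cls <- cls[ok]

  a <- abundance(tableA)[match(ann, canA), samples, drop = FALSE]
  b <- abundance(tableB)[match(ann, canB), samples, drop = FALSE]
  rownames(a) <- rownames(b) <- ann
  out <- list(annotation = data.frame(annotation = ann, lipid_class = cls,
                                      stringsAsFactors = FALSE),
              a = a, b = b, samples = samples)
  class(out) <- "matchedLipidPairs"
  out
}

#' @export
print.matchedLipidPairs <- function(x, ...) {
  cat(sprintf("%d matched lipid pairs across %d shared samples\n",
              nrow(x$annotation), length(x$samples)))
  invisible(x)
}

#' Per-lipid cross-platform correlation
#'
#' Pearson correlation per matched lipid across the shared biological
#' samples, with per-class medians and the overall median. Correlation is
#' invariant to positive affine transforms, so relative abundances correlate
#' directly against absolute concentrations. Pairs with zero variance on
#' either side have undefined correlation; they are flagged and excluded
#' from the medians rather than set to zero.
#'
#' @param pairs a `"matchedLipidPairs"` object from [buildMatchedPairs()].
#' @param logScale correlate log-transformed values (off by default).
#' @return list with `per_lipid` (annotation, class, r, note), `by_class`
#'   (per-class median r and lipid count) and `median_r`.
#' @export
perLipidCorrelation <- function(pairs, logScale = FALSE) {
  stopifnot(inherits(pairs, "matchedLipidPairs"))
  a <- pairs$a; b <- pairs$b
  if (logScale) { a <- log(a); b <- log(b) }
  n <- nrow(a)
  r <- rep(NA_real_, n); note <- character(n)
  for (i in seq_len(n)) {
    xi <- a[i, ]; yi <- b[i, ]
    use <- !is.na(xi) & !is.na(yi)
    if (sum(use) < 3L) { note[i] <- "fewer than 3 complete observations"; next }
    if (stats::sd(xi[use]) == 0 || stats::sd(yi[use]) == 0) {
      note[i] <- "zero variance"; next
    }
    r[i] <- stats::cor(xi[use], yi[use])
  }
  per_lipid <- data.frame(pairs$annotation, r = r, note = note,
                          stringsAsFactors = FALSE)
  classes <- sort(unique(per_lipid$lipid_class))
  by_class <- data.frame(
    lipid_class = classes,
    n = vapply(classes, function(k)
      sum(per_lipid$lipid_class == k & !is.na(r)), integer(1)),
    median_r = vapply(classes, function(k)
      stats::median(r[per_lipid$lipid_class == k], na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_lipid = per_lipid, by_class = by_class,
       median_r = stats::median(r, na.rm = TRUE))
}

#' Dilution-series correlation between platforms
#'
#' Pearson correlation, per internal standard, of the two platforms'
#' responses over a shared dilution ladder -- inter-platform agreement
#' independent of biological variability.
#'
#' @param seriesA,seriesB data.frames with columns `standard_id`, `nominal`,
#'   `response`; ladders must match per standard (>= 3 points).
#' @return list with `per_standard` (standard_id, r) and `median_r`.
#' @export
dilutionCorrelation <- function(seriesA, seriesB) {
  need <- c("standard_id", "nominal", "response")
  stopifnot(all(need %in% names(seriesA)), all(need %in% names(seriesB)))
  ids <- intersect(unique(seriesA$standard_id), unique(seriesB$standard_id))
  if (length(ids) == 0L) .input_error("no shared standards between series")
  r <- vapply(ids, function(id) {
    a <- seriesA[seriesA$standard_id == id, , drop = FALSE]
    b <- seriesB[seriesB$standard_id == id, , drop = FALSE]
    a <- a[order(a$nominal), ]; b <- b[order(b$nominal), ]
    if (nrow(a) < 3L || nrow(b) < 3L || !isTRUE(all.equal(a$nominal, b$nominal)))
      .input_error(sprintf("mismatched dilution ladders for standard '%s'", id))
    stats::cor(a$response, b$response)
  }, numeric(1))
  list(per_standard = data.frame(standard_id = ids, r = r, row.names = NULL,
                                 stringsAsFactors = FALSE),
       median_r = stats::median(r))
}

#' Biological variability versus inter-platform correlation
#'
#' For every matched lipid, pairs its biological variability (CV across
#' samples on platform B) with its inter-platform Pearson r and reports
#' their Spearman rank correlation -- a check of whether lipids that move
#' more across samples agree better between platforms.
#'
#' @param pairs a `"matchedLipidPairs"` object (>= 5 pairs).
#' @param correlation optional result of [perLipidCorrelation()] to reuse;
#'   computed if missing.
#' @return list with `records` (annotation, variability_cv_pct, r) and
#'   `rank_correlation` (`NA` with a note when undefined, e.g. all
#'   variabilities identical).
#' @export
correlationVsVariability <- function(pairs, correlation = NULL) {
  stopifnot(inherits(pairs, "matchedLipidPairs"))
  if (nrow(pairs$annotation) < 5L)
    .input_error("variability association needs at least 5 matched pairs")
  if (is.null(correlation)) correlation <- perLipidCorrelation(pairs)
  variability <- apply(pairs$b, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) NA_real_ else cvPercent(v)
  })
  rec <- data.frame(pairs$annotation,
                    variability_cv_pct = variability,
                    r = correlation$per_lipid$r,
                    stringsAsFactors = FALSE)
  use <- !is.na(rec$variability_cv_pct) & !is.na(rec$r)
  rho <- NA_real_; note <- ""
  if (sum(use) >= 5L && stats::sd(rec$variability_cv_pct[use]) > 0 &&
      stats::sd(rec$r[use]) > 0) {
    rho <- stats::cor(rec$variability_cv_pct[use], rec$r[use],
                      method = "spearman")
  } else {
    note <- "rank correlation undefined (constant input)"
  }
  list(records = rec, rank_correlation = rho, note = note)
}
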