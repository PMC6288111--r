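#' @title Lipids-by-samples abundance container
#'
#' @description
#' `LipidomicsExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' for lipidomics tables: an `abundance` assay (feature intensities, relative
#' abundances, or concentrations in nmol/g) with per-lipid row metadata
#' (name, class, target-level annotation, m/z, adduct, ...) and per-sample
#' column metadata (`role`: biological / blank / pool; `group`: e.g. young /
#' old). The measurement scale is recorded in `metadata(x)$units`.
#'
#' @aliases LipidomicsExperiment-class
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata metadata<-
#' @export
setClass("LipidomicsExperiment", contains = "SummarizedExperiment")

.UNITS <- c("intensity", "relative", "nmol_per_g")
.ROLES <- c("biological", "blank", "pool")

setValidity("LipidomicsExperiment", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (!is.numeric(a)) return("abundance assay must be numeric")
  if (any(a < 0, na.rm = TRUE)) return("abundances must be non-negative")
  u <- S4Vectors::metadata(object)$units
  if (!is.null(u) && !u %in% .UNITS)
    return(sprintf("units must be one of %s", paste(.UNITS, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if ("role" %in% names(cd) && !all(cd$role %in% .ROLES))
    return("sample roles must be biological/blank/pool")
  TRUE
})

#' Construct a LipidomicsExperiment
#'
#' @param abundance numeric matrix, lipids (rows) by samples (columns).
#'   `NA` encodes a missing (undetected) measurement.
#' @param rowData data.frame (or DataFrame) of per-lipid metadata.
#' @param colData data.frame of per-sample metadata; a `role` column
#'   restricted to `"biological"`, `"blank"`, `"pool"` is honoured by the
#'   processing functions (all samples are treated as biological if absent).
#' @param units one of `"intensity"`, `"relative"`, `"nmol_per_g"`.
#' @param platform free-text platform label (e.g. `"untargeted LC-MS"`).
#' @return A [LipidomicsExperiment-class] object.
#' @export
LipidomicsExperiment <- function(abundance, rowData = NULL, colData = NULL,
                                 units = c("intensity", "relative",
                                           "nmol_per_g"),
                                 platform = NA_character_) {
  units <- match.arg(units)
  abundance <- as.matrix(abundance)
  dn <- dimnames(abundance)
  dimnames(abundance) <- NULL
  args <- list(assays = list(abundance = abundance))
  if (!is.null(rowData)) args$rowData <- S4Vectors::DataFrame(rowData)
  if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  if (!is.null(dn)) {
    if (!is.null(dn[[1L]])) rownames(se) <- dn[[1L]]
    if (!is.null(dn[[2L]])) colnames(se) <- dn[[2L]]
  } else if (!is.null(colData) && "sample_id" %in% names(colData)) {
    colnames(se) <- colData$sample_id
  }
  out <- methods::new("LipidomicsExperiment", se)
  S4Vectors::metadata(out)$units <- units
  S4Vectors::metadata(out)$platform <- platform
  methods::validObject(out)
  out
}

#' @rdname abundance
#' @export
setMethod("abundance", "LipidomicsExperiment", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' Sample roles
#' @param x a [LipidomicsExperiment-class].
#' @return Character vector of roles, one per sample; `"biological"` when no
#'   role metadata is present.
#' @export
sampleRole <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("role" %in% names(cd)) as.character(cd$role)
  else rep("biological", ncol(x))
}

#' Measurement units of a table
#' @param x a [LipidomicsExperiment-class].
#' @export
platformUnits <- function(x) S4Vectors::metadata(x)$units

#' Per-sample normalization factors (after IS normalization)
#' @param x a [LipidomicsExperiment-class].
#' @return Named numeric vector, or `NULL` if the table is unnormalized.
#' @export
normalizationFactors <- function(x) S4Vectors::metadata(x)$normalization_factors

#' Per-stage processing log
#' @param x a [LipidomicsExperiment-class].
#' @return data.frame of stages with row counts, or `NULL`.
#' @export
processingLog <- function(x) S4Vectors::metadata(x)$processing_log

.append_log <- function(x, stage, rows_in, rows_out, note = "") {
  log <- S4Vectors::metadata(x)$processing_log
  entry <- data.frame(stage = stage, rows_in = rows_in, rows_out = rows_out,
                      note = note, stringsAsFactors = FALSE)
  S4Vectors::metadata(x)$processing_log <- rbind(log, entry)
  x
}

#' @export
setMethod("show", "LipidomicsExperiment", function(object) {
  roles <- table(sampleRole(object))
  cat(sprintf("LipidomicsExperiment: %d lipids x %d samples [%s%s]\n",
              nrow(object), ncol(object), platformUnits(object),
              if (!is.na(S4Vectors::metadata(object)$platform))
                paste0(", ", S4Vectors::metadata(object)$platform) else ""))
  cat("  samples:",
      paste(sprintf("%s=%d", names(roles), as.integer(roles)), collapse = " "),
      "\n")
  rd <- SummarizedExperiment::rowData(object)
  if (ncol(rd) > 0L)
    cat("  rowData:", paste(names(rd), collapse = ", "), "\n")
})
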