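# Targeted platform quantification: 20-scan MRM intensity sets are trimmed
# and averaged, each analyte is ratioed against its most structurally similar
# deuterated internal standard, and the IS spike concentration converts the
# ratio to nmol/g (assuming 1 ml plasma = 1 g).

#' Trimmed mean of an MRM scan set
#'
#' Of the 20 spectral scans collected per lipid, the 4 scans with the largest
#' absolute deviation from the median of all 20 are discarded and the
#' remaining 16 are averaged. Ties in deviation are broken by discarding the
#' larger intensity first, then by scan order, so the result is deterministic
#' and permutation-invariant up to that rule.
#'
#' @param scans numeric vector of exactly 20 non-negative scan intensities.
#' @return The arithmetic mean of the 16 retained scans.
#' @examples
#' trimmedScanMean(rep(100, 20))
#' trimmedScanMean(c(rep(100, 16), rep(1000, 4)))
#' @export
trimmedScanMean <- function(scans) {
  if (!is.numeric(scans) || length(scans) != 20L || anyNA(scans))
    .input_error("an MRM scan set must hold exactly 20 numeric intensities")
  if (any(scans < 0))
    .input_error("negative scan intensities indicate corrupt upstream data")
  keep <- .trim_keep(scans)
  mean(scans[keep])
}

# indices of the 16 retained scans
.trim_keep <- function(scans, n_drop = 4L) {
  dev <- abs(scans - stats::median(scans))
  drop <- order(-dev, -scans, seq_along(scans))[seq_len(n_drop)]
  setdiff(seq_along(scans), drop)
}

# Row-wise trimmed scan means for a matrix (analytes x 20 scans).
.trimmed_scan_means <- function(m) {
  stopifnot(ncol(m) == 20L)
  apply(m, 1L, function(x) mean(x[.trim_keep(x)]))
}

#' Assign the most structurally similar internal standard
#'
#' Restricted to standards of the analyte's lipid class, structural
#' similarity is resolved as the smallest difference in total carbons, ties
#' broken by the smallest difference in total double bonds, then by
#' `standard_id` lexicographic order -- a deterministic reading of
#' "most structurally similar".
#'
#' @param lipidClass analyte class token.
#' @param sumCarbons,sumDoubleBonds analyte sum composition.
#' @param panel data.frame describing the IS panel with columns
#'   `standard_id`, `lipid_class`, `total_carbons`, `total_double_bonds`,
#'   `concentration_nmol_per_ml`.
#' @return The selected panel row (one-row data.frame).
#' @export
assignInternalStandard <- function(lipidClass, sumCarbons, sumDoubleBonds,
                                   panel) {
  stopifnot(is.data.frame(panel))
  cand <- panel[panel$lipid_class == lipidClass, , drop = FALSE]
  if (nrow(cand) == 0L)
    .input_error(sprintf("no internal standard covers class %s", lipidClass))
  d_c <- abs(cand$total_carbons - sumCarbons)
  d_b <- abs(cand$total_double_bonds - sumDoubleBonds)
  cand[order(d_c, d_b, cand$standard_id)[1L], , drop = FALSE]
}

#' Concentration from an analyte/IS intensity ratio
#'
#' Concentration is the average analyte MRM intensity divided by the average
#' intensity of the assigned internal standard, multiplied by the standard's
#' spiked concentration (nmol/ml), reported in nmol/g under the assumption
#' that 1 ml of plasma weighs 1 g.
#'
#' @param analyteMean trimmed mean analyte intensity (>= 0).
#' @param isMean trimmed mean IS intensity (> 0).
#' @param isConcentration IS spike concentration in nmol/ml (> 0).
#' @return Concentration in nmol/g.
#' @export
computeConcentration <- function(analyteMean, isMean, isConcentration) {
  if (any(analyteMean < 0)) .input_error("analyte intensity must be >= 0")
  if (any(isConcentration <= 0))
    .input_error("IS concentration must be positive")
  if (any(isMean <= 0))
    .input_error("internal standard not detected (zero mean intensity)")
  analyteMean / isMean * isConcentration
}

# Parse an analyte or standard name into (class, total carbons, total double
# bonds, labeled); TAG_FA names use the sum composition.
.quant_key <- function(name) {
  ln <- parseLipidName(name)
  list(lipid_class = ln@lipidClass, sum_carbons = ln@sumCarbons,
       sum_double_bonds = ln@sumDoubleBonds, labeled = ln@deuterium > 0L,
       canonical = formatLipidName(ln))
}

#' Quantify one sample from its MRM scan table
#'
#' Composes [trimmedScanMean()], [assignInternalStandard()] and
#' [computeConcentration()] for every analyte in a sample. Internal-standard
#' scan sets are recognised by their names matching the panel's `lipid_name`
#' column. Failures are reported per lipid (missing concentration with a
#' reason) without aborting the sample.
#'
#' @param scans long-format data.frame for one sample with columns
#'   `lipid_name`, `scan_index` (1--20) and `intensity`.
#' @param panel IS panel data.frame (see [assignInternalStandard()]) plus a
#'   `lipid_name` column giving each standard's own MRM name.
#' @return data.frame with one row per analyte: `lipid_name`,
#'   `concentration_nmol_per_g`, `standard_id`, `note`.
#' @export
quantifySample <- function(scans, panel) {
  stopifnot(is.data.frame(scans),
            all(c("lipid_name", "scan_index", "intensity") %in% names(scans)))
  if (nrow(scans) == 0L)
    return(data.frame(lipid_name = character(0),
                      concentration_nmol_per_g = numeric(0),
                      standard_id = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  split_scans <- split(scans$intensity[order(scans$lipid_name,
                                             scans$scan_index)],
                       sort(scans$lipid_name))
  means <- vapply(split_scans, trimmedScanMean, numeric(1))

  is_names <- panel$lipid_name
  is_means <- means[names(means) %in% is_names]
  analytes <- setdiff(names(means), is_names)

  res <- lapply(analytes, function(nm) {
    tryCatch({
      key <- .quant_key(nm)
      std <- assignInternalStandard(key$lipid_class, key$sum_carbons,
                                    key$sum_double_bonds, panel)
      if (!std$lipid_name %in% names(is_means))
        .input_error(sprintf("standard '%s' has no scans in this sample",
                             std$standard_id))
      conc <- computeConcentration(means[[nm]], is_means[[std$lipid_name]],
                                   std$concentration_nmol_per_ml)
      data.frame(lipid_name = nm, concentration_nmol_per_g = conc,
                 standard_id = std$standard_id, note = "",
                 stringsAsFactors = FALSE)
    }, lipidbridgeError = function(e) {
      data.frame(lipid_name = nm, concentration_nmol_per_g = NA_real_,
                 standard_id = NA_character_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quantify a whole targeted study
#'
#' Vectorized multi-sample version of [quantifySample()]: every
#' (sample, lipid) pair must carry exactly 20 scans. Returns the
#' concentration matrix as a [LipidomicsExperiment-class] (nmol/g) along
#' with an assignment audit.
#'
#' @param scans long data.frame with columns `sample_id`, `lipid_name`,
#'   `scan_index`, `intensity`.
#' @param panel IS panel data.frame (see [quantifySample()]).
#' @param groups optional named vector mapping sample ids to group labels,
#'   stored in `colData`.
#' @return A [LipidomicsExperiment-class]; `metadata(x)$is_assignment` holds
#'   the per-lipid standard assignment audit.
#' @export
quantifyStudy <- function(scans, panel, groups = NULL) {
  stopifnot(all(c("sample_id", "lipid_name", "scan_index", "intensity")
                %in% names(scans)))
  ord <- order(scans$sample_id, scans$lipid_name, scans$scan_index)
  s <- scans[ord, , drop = FALSE]
  combos <- paste(s$sample_id, s$lipid_name, sep = "\r")
  n_per <- table(combos)
  if (any(n_per != 20L))
    .input_error("every (sample, lipid) pair needs exactly 20 scans")
  m <- matrix(s$intensity, ncol = 20L, byrow = TRUE)
  first <- !duplicated(combos)
  sample_of <- s$sample_id[first]
  lipid_of <- s$lipid_name[first]
  means <- .trimmed_scan_means(m)

  samples <- sort(unique(sample_of))
  is_names <- panel$lipid_name
  analytes <- sort(setdiff(unique(lipid_of), is_names))

  # one structural assignment per analyte, reused across samples
  keys <- lapply(analytes, function(nm) {
    tryCatch({
      key <- .quant_key(nm)
      std <- assignInternalStandard(key$lipid_class, key$sum_carbons,
                                    key$sum_double_bonds, panel)
      c(key[c("lipid_class", "canonical")],
        list(standard_id = std$standard_id, is_name = std$lipid_name,
             is_conc = std$concentration_nmol_per_ml, note = ""))
    }, lipidbridgeError = function(e) {
      list(lipid_class = NA_character_, canonical = NA_character_,
           standard_id = NA_character_, is_name = NA_character_,
           is_conc = NA_real_, note = conditionMessage(e))
    })
  })
  audit <- data.frame(
    lipid_name = analytes,
    lipid_class = vapply(keys, `[[`, character(1), "lipid_class"),
    canonical = vapply(keys, `[[`, character(1), "canonical"),
    standard_id = vapply(keys, `[[`, character(1), "standard_id"),
    note = vapply(keys, `[[`, character(1), "note"),
    stringsAsFactors = FALSE)

  conc <- matrix(NA_real_, nrow = length(analytes), ncol = length(samples),
                 dimnames = list(analytes, samples))
  mean_lookup <- split(seq_along(means), sample_of)
  for (sid in samples) {
    idx <- mean_lookup[[sid]]
    mu <- means[idx]
    names(mu) <- lipid_of[idx]
    for (j in seq_along(analytes)) {
      k <- keys[[j]]
      if (is.na(k$standard_id) || !analytes[j] %in% names(mu)) next
      if (!k$is_name %in% names(mu) || mu[[k$is_name]] <= 0) next
      conc[j, sid] <- mu[[analytes[j]]] / mu[[k$is_name]] * k$is_conc
    }
  }

  cd <- data.frame(sample_id = samples, role = "biological",
                   stringsAsFactors = FALSE)
  if (!is.null(groups)) cd$group <- unname(groups[samples])
  out <- LipidomicsExperiment(
    conc,
    rowData = audit[, c("lipid_name", "lipid_class", "canonical",
                        "standard_id")],
    colData = cd, units = "nmol_per_g", platform = "targeted MRM")
  S4Vectors::metadata(out)$is_assignment <- audit
  out
}

#' Read a long-format MRM scan table
#' @param path CSV with columns `sample_id`, `lipid_name`, `q1`, `q3`,
#'   `scan_index`, `intensity`.
#' @return data.frame.
#' @export
readScanTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "lipid_name", "scan_index", "intensity")
  if (!all(need %in% names(df)))
    .input_error(sprintf("scan table lacks column(s): %s",
                         paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' Read an internal-standard panel
#'
#' Parses each standard's lipid name to derive its class and total
#' carbons/double bonds for structural matching.
#'
#' @param path CSV with columns `standard_id`, `lipid_name`,
#'   `concentration_nmol_per_ml`.
#' @return Panel data.frame ready for [assignInternalStandard()].
#' @export
readIsPanel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("standard_id", "lipid_name", "concentration_nmol_per_ml")
  if (!all(need %in% names(df)))
    .input_error(sprintf("IS panel lacks column(s): %s",
                         paste(setdiff(need, names(df)), collapse = ", ")))
  keys <- lapply(df$lipid_name, .quant_key)
  df$lipid_class <- vapply(keys, `[[`, character(1), "lipid_class")
  df$total_carbons <- vapply(keys, function(k) as.integer(k$sum_carbons),
                             integer(1))
  df$total_double_bonds <- vapply(keys,
                                  function(k) as.integer(k$sum_double_bonds),
                                  integer(1))
  df
}

#' Write a concentration matrix and its assignment audit
#' @param x a [LipidomicsExperiment-class] from [quantifyStudy()].
#' @param path output CSV path for the matrix.
#' @param auditPath optional CSV path for the IS assignment audit.
#' @return `path`, invisibly.
#' @export
writeConcentrationMatrix <- function(x, path, auditPath = NULL) {
  df <- data.frame(lipid_name = rownames(x), abundance(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_report_csv(df, path)
  if (!is.null(auditPath))
    .write_report_csv(S4Vectors::metadata(x)$is_assignment, auditPath)
  invisible(path)
}
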