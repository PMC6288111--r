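# Precision and accuracy metrics: intra-/inter-day coefficients of
# variation from replicate injections, and calibration-curve r^2 / percent
# accuracy from 7-point internal-standard dilution series.

#' Coefficient of variation in percent
#'
#' 100 times the sample standard deviation (n - 1 denominator) divided by
#' the mean. Invariant under positive rescaling of the measurements.
#'
#' @param values numeric vector of at least two measurements with nonzero
#'   mean.
#' @return CV in percent.
#' @examples
#' cvPercent(c(8, 10, 12))  # 20
#' @export
cvPercent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    .input_error("CV needs at least two measurements")
  m <- mean(values)
  if (m == 0) .input_error("CV is undefined for zero-mean measurements")
  100 * stats::sd(values) / m
}

#' Intra-day precision
#'
#' CV of the five replicate injections acquired on a single day.
#'
#' @param values the day's five replicate measurements.
#' @return Intra-day CV in percent.
#' @export
intradayPrecision <- function(values) {
  if (length(values) != 5L)
    .input_error("intra-day precision expects 5 replicate injections")
  cvPercent(values)
}

#' Inter-day precision
#'
#' CV between the medians of five replicate injections across three
#' consecutive days: within-day scatter does not contribute, only day-to-day
#' movement of the daily medians.
#'
#' @param values replicate measurements (3 days x 5 replicates).
#' @param days parallel vector of day labels; exactly 3 distinct days with 5
#'   replicates each.
#' @return Inter-day CV in percent.
#' @export
interdayPrecision <- function(values, days) {
  stopifnot(length(values) == length(days))
  tab <- table(days)
  if (length(tab) != 3L || any(tab != 5L))
    .input_error("inter-day precision expects 3 days x 5 replicates")
  medians <- tapply(values, days, stats::median)
  cvPercent(as.numeric(medians))
}

#' Fit a calibration curve and inverse-predict the recommended level
#'
#' Ordinary least squares of measured response on nominal concentration
#' (raw axes); the determination coefficient is the squared Pearson
#' correlation of the points used. The calculated concentration at the
#' recommended spike-in level is obtained by inverse prediction,
#' (response at that level - intercept) / slope. Optionally the
#' highest-concentration point is dropped before fitting, the remedy for
#' detector saturation at the top of the series.
#'
#' @param nominal strictly increasing nominal concentrations (the dilution
#'   ladder).
#' @param response measured responses, parallel to `nominal`.
#' @param recommended the recommended concentration; must be one of the
#'   ladder points (and never the dropped top point).
#' @param dropHighest drop the highest-concentration point before fitting.
#' @return list with `slope`, `intercept`, `r_squared`, `calculated`
#'   (inverse-predicted concentration at the recommended level) and
#'   `n_points`.
#' @export
fitCalibration <- function(nominal, response, recommended,
                           dropHighest = FALSE) {
  stopifnot(length(nominal) == length(response))
  if (is.unsorted(nominal, strictly = TRUE))
    .input_error("nominal concentrations must be strictly increasing")
  if (!recommended %in% nominal)
    .input_error("the recommended level must be one of the ladder points")
  resp_rec <- response[match(recommended, nominal)]
  if (dropHighest) {
    if (recommended == max(nominal))
      .input_error("cannot drop the point carrying the recommended level")
    keep <- nominal != max(nominal)
    nominal <- nominal[keep]; response <- response[keep]
  }
  if (length(nominal) < 3L)
    .input_error("calibration needs at least 3 points after any drop")
  slope <- stats::cov(nominal, response) / stats::var(nominal)
  intercept <- mean(response) - slope * mean(nominal)
  if (slope == 0)
    .input_error("zero calibration slope; inverse prediction impossible")
  r2 <- stats::cor(nominal, response)^2
  list(slope = slope, intercept = intercept, r_squared = r2,
       calculated = (resp_rec - intercept) / slope,
       n_points = length(nominal))
}

#' Percent accuracy against a known concentration
#'
#' `|calculated - actual| / actual * 100`; symmetric in the sign of the
#' deviation and invariant under joint positive rescaling.
#'
#' @param calculated calculated concentration(s).
#' @param actual true (spiked) concentration(s), > 0.
#' @return Accuracy in percent (0 is perfect).
#' @export
accuracyPercent <- function(calculated, actual) {
  if (any(actual <= 0)) .input_error("actual concentration must be positive")
  abs((calculated - actual) / actual) * 100
}

#' Platform QC summary
#'
#' Per-analyte intra-day CV (first day), inter-day CV, calibration r^2 and
#' percent accuracy at the recommended level, plus the platform medians of
#' each metric (standard order statistic; mean of the central two for even
#' counts). Per-analyte failures are reported as missing entries with the
#' reason, not as a summary failure.
#'
#' @param replicates data.frame with columns `analyte`, `day`, `replicate`,
#'   `value` (5 replicates on each of 3 days).
#' @param calibrations data.frame with columns `standard_id`, `nominal`,
#'   `response`, `recommended` (logical flag on the recommended ladder
#'   point); 7 points per standard.
#' @param dropHighest passed to [fitCalibration()].
#' @return list with `analytes` (per-analyte precision data.frame),
#'   `calibration` (per-standard r^2/accuracy data.frame) and `medians`
#'   (named numeric vector of platform medians).
#' @export
qcSummary <- function(replicates, calibrations = NULL, dropHighest = FALSE) {
  stopifnot(all(c("analyte", "day", "replicate", "value")
                %in% names(replicates)))
  analytes <- sort(unique(replicates$analyte))
  if (length(analytes) == 0L) {
    empty <- data.frame(analyte = character(0),
                        intraday_cv_pct = numeric(0),
                        interday_cv_pct = numeric(0))
    return(list(analytes = empty, calibration = NULL,
                medians = c(median_intraday_cv_pct = NA_real_,
                            median_interday_cv_pct = NA_real_)))
  }
  prec <- lapply(analytes, function(a) {
    sub <- replicates[replicates$analyte == a, , drop = FALSE]
    intra <- tryCatch({
      d1 <- sub[sub$day == min(sub$day), , drop = FALSE]
      intradayPrecision(d1$value)
    }, lipidbridgeError = function(e) NA_real_)
    inter <- tryCatch(interdayPrecision(sub$value, sub$day),
                      lipidbridgeError = function(e) NA_real_)
    data.frame(analyte = a, intraday_cv_pct = intra, interday_cv_pct = inter,
               stringsAsFactors = FALSE)
  })
  prec <- do.call(rbind, prec)

  cal <- NULL
  if (!is.null(calibrations)) {
    stopifnot(all(c("standard_id", "nominal", "response", "recommended")
                  %in% names(calibrations)))
    ids <- sort(unique(calibrations$standard_id))
    cal <- lapply(ids, function(id) {
      sub <- calibrations[calibrations$standard_id == id, , drop = FALSE]
      sub <- sub[order(sub$nominal), , drop = FALSE]
      rec <- sub$nominal[sub$recommended][1L]
      tryCatch({
        fit <- fitCalibration(sub$nominal, sub$response, rec,
                              dropHighest = dropHighest)
        data.frame(standard_id = id, r_squared = fit$r_squared,
                   calculated = fit$calculated,
                   accuracy_pct = accuracyPercent(fit$calculated, rec),
                   note = "", stringsAsFactors = FALSE)
      }, lipidbridgeError = function(e) {
        data.frame(standard_id = id, r_squared = NA_real_,
                   calculated = NA_real_, accuracy_pct = NA_real_,
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
    })
    cal <- do.call(rbind, cal)
  }

  medians <- c(
    median_intraday_cv_pct = stats::median(prec$intraday_cv_pct, na.rm = TRUE),
    median_interday_cv_pct = stats::median(prec$interday_cv_pct, na.rm = TRUE))
  if (!is.null(cal)) {
    medians <- c(medians,
      median_r_squared = stats::median(cal$r_squared, na.rm = TRUE),
      median_accuracy_pct = stats::median(cal$accuracy_pct, na.rm = TRUE))
  }
  list(analytes = prec, calibration = cal, medians = medians)
}

#' Read a replicate-injection table
#' @param path CSV with columns `analyte`, `day`, `replicate`, `value`.
#' @export
readReplicates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "day", "replicate", "value")
  if (!all(need %in% names(df)))
    .input_error(sprintf("replicate table lacks column(s): %s",
                         paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' Read a calibration-series table
#' @param path CSV with columns `standard_id`, `nominal`, `response`,
#'   `recommended`.
#' @export
readCalibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("standard_id", "nominal", "response", "recommended")
  if (!all(need %in% names(df)))
    .input_error(sprintf("calibration table lacks column(s): %s",
                         paste(setdiff(need, names(df)), collapse = ", ")))
  df$recommended <- as.logical(df$recommended)
  df
}
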