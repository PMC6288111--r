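# Two-group differential analysis (old vs young): Welch's unequal-variance
# t-test per lipid, Benjamini-Hochberg FDR control used as the q-value,
# direction calls, per-class totals, and cross-platform consensus of
# deregulated lipids.

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p value. The statistic is `mean(x) - mean(y)` over the
#' pooled standard error, so the sign follows the first argument.
#'
#' @param x,y numeric vectors (>= 2 values each; at least one group with
#'   nonzero variance).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welchTTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    .input_error("Welch's test needs at least 2 values per group")
  res <- rowWelchTest(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  if (is.na(res$statistic[1L]))
    .input_error("both groups have zero variance; test undefined")
  list(statistic = res$statistic[1L], df = res$df[1L],
       p_value = res$p_value[1L])
}

#' Row-wise Welch tests
#'
#' Vectorized Welch's t-test across the rows of two matrices (same row
#' count, columns = samples per group). Rows where both groups have zero
#' variance get `NA` results.
#'
#' @param x,y numeric matrices with equal row counts.
#' @return data.frame with columns `statistic`, `df`, `p_value`.
#' @export
rowWelchTest <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / (nx - 1L)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / (ny - 1L)
  ax <- vx / nx; ay <- vy / ny
  se2 <- ax + ay
  stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / (ax^2 / (nx - 1L) + ay^2 / (ny - 1L))
  p <- 2 * stats::pt(-abs(stat), df)
  bad <- nx < 2L | ny < 2L | se2 == 0
  stat[bad] <- NA_real_; df[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(statistic = stat, df = df, p_value = p)
}

#' Benjamini-Hochberg adjusted p values as q values
#'
#' Step-up adjustment with enforced monotonicity (the classical BH
#' procedure, no null-proportion estimation), used here as the q-value
#' estimate. Order-preserving: a smaller p never receives a larger q.
#'
#' @param p_values numeric vector of p values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return Vector of q values, same length and order as the input.
#' @export
fdrAdjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    .input_error("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Two-group differential abundance analysis
#'
#' Welch's t-test per lipid between the `old` and `young` groups (statistic
#' and direction are old relative to young), BH/q-value FDR adjustment, and
#' a significance call at the stated FDR: a lipid is significant when its q
#' value is at or below the threshold. Values are tested untransformed by
#' default.
#'
#' @param x a [LipidomicsExperiment-class] or numeric matrix
#'   (lipids x samples).
#' @param groups factor or character vector of group labels per sample,
#'   containing exactly the levels `"young"` and `"old"`.
#' @param fdr significance threshold on the q value (default 0.05).
#' @param logTransform test log-transformed values (off by default).
#' @return data.frame with one row per lipid: `lipid`, `annotation` and
#'   `lipid_class` (when row metadata is available), group means, `statistic`,
#'   `df`, `p_value`, `q_value`, `direction`
#'   (increased/decreased/unchanged with age) and `significant`.
#' @export
differentialAnalysis <- function(x, groups, fdr = 0.05,
                                 logTransform = FALSE) {
  ann <- NULL; cls <- NULL
  if (is(x, "LipidomicsExperiment")) {
    rd <- SummarizedExperiment::rowData(x)
    if ("canonical" %in% names(rd)) ann <- as.character(rd$canonical)
    if ("lipid_class" %in% names(rd)) cls <- as.character(rd$lipid_class)
    m <- abundance(x)
  } else {
    m <- as.matrix(x)
  }
  groups <- as.character(groups)
  if (!setequal(unique(groups), c("young", "old")))
    .input_error("groups must contain exactly the labels 'young' and 'old'")
  if (ncol(m) != length(groups))
    .input_error("one group label per sample is required")
  old <- m[, groups == "old", drop = FALSE]
  young <- m[, groups == "young", drop = FALSE]
  if (ncol(old) < 2L || ncol(young) < 2L)
    .input_error("each group needs at least 2 samples")
  if (logTransform) { old <- log(old); young <- log(young) }

  wt <- rowWelchTest(old, young)
  q <- fdrAdjust(wt$p_value)
  mean_old <- rowMeans(old, na.rm = TRUE)
  mean_young <- rowMeans(young, na.rm = TRUE)
  significant <- !is.na(q) & q <= fdr
  direction <- ifelse(!significant, "unchanged",
                      ifelse(mean_old > mean_young, "increased", "decreased"))
  out <- data.frame(
    lipid = if (!is.null(rownames(m))) rownames(m)
            else sprintf("lipid_%04d", seq_len(nrow(m))),
    mean_young = if (logTransform) rowMeans(exp(young), na.rm = TRUE)
                 else mean_young,
    mean_old = if (logTransform) rowMeans(exp(old), na.rm = TRUE)
               else mean_old,
    statistic = wt$statistic, df = wt$df, p_value = wt$p_value,
    q_value = q, direction = direction, significant = significant,
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(ann)) out <- cbind(out[1L], annotation = ann, out[-1L])
  if (!is.null(cls)) out <- cbind(out[seq_len(2L)], lipid_class = cls,
                                  out[-seq_len(2L)])
  out
}

#' Count deregulation direction calls
#'
#' @param results data.frame from [differentialAnalysis()].
#' @param fdr threshold used to (re)derive significance from the q values.
#' @return list with `results` (direction calls recomputed at `fdr`) and
#'   `counts` (named vector: increased, decreased, unchanged; exhaustive and
#'   mutually exclusive, summing to the panel size).
#' @export
classifyDeregulated <- function(results, fdr = 0.05) {
  stopifnot(all(c("q_value", "mean_young", "mean_old") %in% names(results)))
  significant <- !is.na(results$q_value) & results$q_value <= fdr
  direction <- ifelse(!significant, "unchanged",
                      ifelse(results$mean_old > results$mean_young,
                             "increased", "decreased"))
  results$direction <- direction
  results$significant <- significant
  counts <- c(increased = sum(direction == "increased"),
              decreased = sum(direction == "decreased"),
              unchanged = sum(direction == "unchanged"))
  list(results = results, counts = counts)
}

#' Class-total differential tests
#'
#' Sums member lipids per class and sample, adds a global total, and applies
#' Welch's test to each (raw p values; class-level results are reported
#' without multiplicity correction).
#'
#' @param x a [LipidomicsExperiment-class] or matrix (lipids x samples).
#' @param classes character vector mapping every row to one lipid class
#'   (taken from `rowData(x)$lipid_class` when omitted).
#' @param groups group labels per sample (`"young"`/`"old"`).
#' @return data.frame with one row per class plus `"TOTAL"`: per-group mean
#'   totals, `statistic`, `p_value`.
#' @export
classTotalsTest <- function(x, classes = NULL, groups) {
  if (is(x, "LipidomicsExperiment")) {
    if (is.null(classes))
      classes <- as.character(SummarizedExperiment::rowData(x)$lipid_class)
    m <- abundance(x)
  } else {
    m <- as.matrix(x)
  }
  if (is.null(classes) || length(classes) != nrow(m) || anyNA(classes))
    .input_error("every lipid must be mapped to exactly one class")
  m0 <- m; m0[is.na(m0)] <- 0
  totals <- rowsum(m0, classes)
  totals <- rbind(totals, TOTAL = colSums(m0))
  groups <- as.character(groups)
  old <- totals[, groups == "old", drop = FALSE]
  young <- totals[, groups == "young", drop = FALSE]
  wt <- rowWelchTest(old, young)
  data.frame(lipid_class = rownames(totals),
             mean_young = rowMeans(young), mean_old = rowMeans(old),
             statistic = wt$statistic, p_value = wt$p_value,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-platform consensus of deregulated lipids
#'
#' Among significantly deregulated lipids on each platform (excluded classes
#' removed, TAG by default because of nomenclature discrepancies), counts
#' the annotations significant on both platforms with the same direction;
#' shared annotations disagreeing in direction are reported separately.
#'
#' @param resultsA,resultsB data.frames from [differentialAnalysis()] with
#'   an `annotation` column.
#' @param excludeClasses classes excluded from the comparison.
#' @return list with `shared_same_direction` (data.frame of annotation and
#'   direction), `discordant`, `venn` (a_only, shared, b_only counts over
#'   same-direction sharing) and the per-platform deregulated counts.
#' @export
crossPlatformConsensus <- function(resultsA, resultsB,
                                   excludeClasses = "TAG") {
  .sig <- function(res) {
    stopifnot(all(c("annotation", "significant", "direction") %in% names(res)))
    res <- res[res$significant & !is.na(res$annotation), , drop = FALSE]
    if ("lipid_class" %in% names(res))
      res <- res[!res$lipid_class %in% excludeClasses, , drop = FALSE]
    res[!duplicated(res$annotation), c("annotation", "direction")]
  }
  a <- .sig(resultsA); b <- .sig(resultsB)
  shared_ann <- intersect(a$annotation, b$annotation)
  dir_a <- a$direction[match(shared_ann, a$annotation)]
  dir_b <- b$direction[match(shared_ann, b$annotation)]
  same <- dir_a == dir_b
  list(
    shared_same_direction = data.frame(annotation = shared_ann[same],
                                       direction = dir_a[same],
                                       stringsAsFactors = FALSE),
    discordant = data.frame(annotation = shared_ann[!same],
                            direction_a = dir_a[!same],
                            direction_b = dir_b[!same],
                            stringsAsFactors = FALSE),
    venn = c(a_only = nrow(a) - sum(same), shared = sum(same),
             b_only = nrow(b) - sum(same)),
    n_deregulated_a = nrow(a), n_deregulated_b = nrow(b))
}
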