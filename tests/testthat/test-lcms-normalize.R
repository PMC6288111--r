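# Untargeted feature-table processing stages.

.mk_table <- function(mat, roles = NULL, lipid = NULL, adduct = NULL) {
  n <- nrow(mat)
  if (is.null(roles)) roles <- rep("biological", ncol(mat))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("F%03d", seq_len(n))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  rd <- data.frame(feature_id = rownames(mat),
                   lipid_name = if (is.null(lipid)) rownames(mat) else lipid,
                   adduct = if (is.null(adduct)) "[M+H]+" else adduct,
                   stringsAsFactors = FALSE)
  LipidomicsExperiment(mat, rowData = rd,
                       colData = data.frame(sample_id = colnames(mat),
                                            role = roles),
                       units = "intensity")
}

test_that("blank-dominated features are dropped and clean features kept", {
  mat <- rbind(clean = c(100, 120, 0),
               absent_in_blank = c(50, 60, 0),
               contaminant = c(80, 90, 85),
               equal_blank = c(100, 100, 100))
  x <- .mk_table(mat, roles = c("biological", "biological", "blank"))
  out <- removeBlankFeatures(x, blankRatio = 0.5)
  expect_setequal(rownames(out), c("clean", "absent_in_blank"))
  # protected features survive regardless
  out2 <- removeBlankFeatures(x, blankRatio = 0.5, protect = "contaminant")
  expect_true("contaminant" %in% rownames(out2))
  # no blanks: warning, no-op
  y <- .mk_table(mat[, 1:2], roles = rep("biological", 2))
  expect_warning(out3 <- removeBlankFeatures(y), "no blank")
  expect_identical(nrow(out3), nrow(y))
})

test_that("planted blank-only contaminants are exactly the features the
           generator marked", {
  st <- generateStudy(smallConfig(seed = 21L))
  out <- removeBlankFeatures(st$platformA, protect = st$isFeatures)
  dropped <- setdiff(rownames(st$platformA), rownames(out))
  expect_setequal(dropped, grep("^BLK", rownames(st$platformA), value = TRUE))
})

test_that("two-IS normalization removes per-sample multiplicative scale", {
  set.seed(5)
  truth <- matrix(rlnorm(40, log(1000), 1), nrow = 8)
  factors <- rlnorm(5, 0, 0.4)
  mat <- rbind(sweep(truth, 2, factors, "*"),
               IS1 = 1e5 * factors, IS2 = 7e4 * factors)
  rownames(mat)[1:8] <- sprintf("F%03d", 1:8)
  x <- .mk_table(mat)
  out <- normalizeBySpikedIS(x, c("IS1", "IS2"))
  expect_identical(platformUnits(out), "relative")
  expect_false(any(c("IS1", "IS2") %in% rownames(out)))
  # factors average to one and recover the planted scale exactly
  f <- normalizationFactors(out)
  expect_equal(mean(f), 1, tolerance = 1e-12)
  expect_gt(cor(f, factors), 0.99)
  # the planted per-sample scale is removed exactly at zero residual noise
  # (up to one global constant, the mean of the planted factors)
  expect_equal(unname(abundance(out)), truth * mean(factors),
               tolerance = 1e-10)
})

test_that("a sample with all intensities doubled normalizes back to its
           twin", {
  set.seed(6)
  base <- rlnorm(6, log(500), 0.5)
  mat <- cbind(S1 = c(base, 1000, 800), S2 = 2 * c(base, 1000, 800))
  rownames(mat) <- c(sprintf("F%03d", 1:6), "IS1", "IS2")
  out <- normalizeBySpikedIS(.mk_table(mat), c("IS1", "IS2"))
  expect_equal(abundance(out)[, "S1"], abundance(out)[, "S2"],
               tolerance = 1e-12)
  # IS constant across samples: factors are all one, table unchanged
  mat2 <- cbind(S1 = c(base, 1000, 800), S2 = c(2 * base, 1000, 800))
  rownames(mat2) <- rownames(mat)
  out2 <- normalizeBySpikedIS(.mk_table(mat2), c("IS1", "IS2"))
  expect_equal(unname(normalizationFactors(out2)), c(1, 1))
  expect_equal(unname(abundance(out2)), unname(mat2[1:6, ]))
  # an IS missing in one sample is a named error
  mat3 <- mat; mat3["IS2", "S2"] <- 0
  expect_error(normalizeBySpikedIS(.mk_table(mat3), c("IS1", "IS2")),
               regexp = "S2", class = "lipidInputError")
})

test_that("the presence filter is strictly greater than the threshold", {
  mat <- rbind(five_of_ten = c(rep(10, 5), rep(NA, 5)),
               six_of_ten = c(rep(10, 6), rep(NA, 4)),
               zeros_dont_count = c(rep(10, 5), rep(0, 5)),
               all_missing = rep(NA_real_, 10))
  out <- filterByPresence(.mk_table(mat), minFraction = 0.5)
  expect_identical(rownames(out), "six_of_ten")
})

test_that("minimum imputation fills gaps with the per-lipid minimum and is
           idempotent", {
  mat <- rbind(a = c(10, 20, NA), b = c(5, 4, 8), c = c(0, 3, 6))
  out <- imputeMinimum(.mk_table(mat))
  expect_equal(unname(abundance(out)["a", ]), c(10, 20, 10))
  expect_equal(unname(abundance(out)["c", ]), c(3, 3, 6))
  again <- imputeMinimum(out)
  expect_equal(abundance(again), abundance(out))
  bad <- .mk_table(rbind(empty = c(NA_real_, NA_real_, NA_real_)))
  expect_error(imputeMinimum(bad), class = "lipidInputError")
})

test_that("adduct collapsing keeps the most abundant ion with a
           lexicographic tie rule", {
  mat <- rbind(h = c(1e6, 1e6), na = c(1e5, 1e5),
               single = c(50, 60), t1 = c(100, 100), t2 = c(100, 100))
  x <- .mk_table(mat,
                 lipid = c("PC(34:1)", "PC(34:1)", "PE(36:2)",
                           "SM(d38:1)", "SM(d38:1)"),
                 adduct = c("[M+H]+", "[M+Na]+", "[M+H]+",
                            "[M+Na]+", "[M+H]+"))
  out <- selectPrimaryAdduct(x)
  rd <- SummarizedExperiment::rowData(out)
  expect_identical(nrow(out), 3L)
  expect_identical(rd$adduct[rd$lipid_name == "PC(34:1)"], "[M+H]+")
  # exact tie: lexicographically first adduct wins deterministically
  expect_identical(rd$adduct[rd$lipid_name == "SM(d38:1)"], "[M+H]+")
})

test_that("the composed pipeline never grows rows and keeps only biological
           samples", {
  st <- generateStudy(smallConfig(seed = 17L))
  out <- processLcms(st$platformA, st$isFeatures)
  log <- processingLog(out)
  expect_identical(log$stage, c("remove_blank", "normalize_is",
                                "presence_filter", "impute_minimum",
                                "adduct_collapse"))
  expect_true(all(diff(c(log$rows_in[1], log$rows_out)) <= 0))
  expect_true(all(sampleRole(out) == "biological"))
  expect_false(anyNA(abundance(out)))
  expect_identical(ncol(out), st$config$nYoung + st$config$nOld)
  # planted low-presence features were filtered out
  low <- st$truthA$feature_id[st$truthA$low_presence]
  expect_false(any(low %in% rownames(out)))
})

test_that("feature tables round-trip through CSV files", {
  tmp <- withr::local_tempdir()
  st <- generateStudy(smallConfig(seed = 4L))
  rd <- as.data.frame(SummarizedExperiment::rowData(st$platformA))
  feat <- cbind(rd[, c("feature_id", "mz", "rt", "adduct", "lipid_name")],
                as.data.frame(abundance(st$platformA)))
  write.csv(feat, file.path(tmp, "features.csv"), row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(st$platformA))
  write.csv(cd, file.path(tmp, "samples.csv"), row.names = FALSE)
  x <- readFeatureTable(file.path(tmp, "features.csv"),
                        file.path(tmp, "samples.csv"))
  expect_s4_class(x, "LipidomicsExperiment")
  expect_identical(dim(x), dim(st$platformA))
  expect_equal(abundance(x), abundance(st$platformA), ignore_attr = TRUE)
})
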