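# MRM scan trimming, internal-standard assignment and concentration
# estimation.

test_that("the trimmed scan mean discards the four most deviant scans", {
  expect_equal(trimmedScanMean(rep(100, 20)), 100)
  expect_equal(trimmedScanMean(c(rep(100, 16), rep(1000, 4))), 100)
  expect_equal(trimmedScanMean(1:20), mean(sort(1:20)[3:18]))
  expect_error(trimmedScanMean(1:19), class = "lipidInputError")
  expect_error(trimmedScanMean(1:21), class = "lipidInputError")
  expect_error(trimmedScanMean(c(-1, rep(1, 19))), class = "lipidInputError")
})

test_that("the trimming rule matches a brute-force deviation ranking on
           random scan sets", {
  set.seed(101)
  for (i in 1:100) {
    x <- round(rlnorm(20, log(1000), 0.4), if (i %% 3 == 0) 0 else 3)
    expect_equal(trimmedScanMean(x), oracleTrimmedMean(x), tolerance = 1e-12)
  }
})

test_that("the trimmed mean is permutation-invariant and bounded by the
           retained scans", {
  set.seed(7)
  x <- rlnorm(20, log(500), 0.3)
  m <- trimmedScanMean(x)
  for (i in 1:20) expect_equal(trimmedScanMean(sample(x)), m)
  expect_gte(m, min(x)); expect_lte(m, max(x))
})

test_that("internal-standard assignment minimizes carbon then double-bond
           distance with a deterministic id tie-break", {
  panel <- data.frame(
    standard_id = c("PE-IS-1", "PE-IS-2", "PE-IS-3", "CE-IS-1", "CE-IS-2"),
    lipid_class = c("PE", "PE", "PE", "CE", "CE"),
    total_carbons = c(34L, 36L, 40L, 16L, 18L),
    total_double_bonds = c(1L, 2L, 6L, 0L, 1L),
    concentration_nmol_per_ml = 5,
    stringsAsFactors = FALSE)
  expect_identical(
    assignInternalStandard("PE", 36L, 2L, panel)$standard_id, "PE-IS-2")
  expect_identical(
    assignInternalStandard("CE", 20L, 4L, panel)$standard_id, "CE-IS-2")
  expect_error(assignInternalStandard("FFA", 18L, 1L, panel),
               regexp = "FFA", class = "lipidInputError")
  # carbons tie resolved by double bonds, then lexicographic id
  tie <- data.frame(standard_id = c("Z-IS", "A-IS"), lipid_class = "PC",
                    total_carbons = 34L, total_double_bonds = c(2L, 2L),
                    concentration_nmol_per_ml = 1)
  expect_identical(assignInternalStandard("PC", 34L, 1L, tie)$standard_id,
                   "A-IS")
})

test_that("concentration is the intensity ratio scaled by the IS spike", {
  expect_equal(computeConcentration(1000, 1000, 5), 5)
  expect_equal(computeConcentration(2000, 1000, 5), 10)
  expect_equal(computeConcentration(0, 1000, 5), 0)
  expect_error(computeConcentration(10, 0, 5), class = "lipidInputError")
  expect_error(computeConcentration(10, 100, 0), class = "lipidInputError")
})

test_that("quantifySample composes trimming, assignment and ratioing", {
  panel <- data.frame(standard_id = "PE-IS-1", lipid_name = "d9-PE(36:2)",
                      lipid_class = "PE", total_carbons = 36L,
                      total_double_bonds = 2L,
                      concentration_nmol_per_ml = 5,
                      stringsAsFactors = FALSE)
  scans <- data.frame(
    lipid_name = rep(c("PE(36:2)", "d9-PE(36:2)"), each = 20),
    scan_index = rep(1:20, 2),
    intensity = rep(c(200, 100), each = 20))
  out <- quantifySample(scans, panel)
  expect_equal(out$concentration_nmol_per_g, 10)
  expect_identical(out$standard_id, "PE-IS-1")

  # empty input gives an empty column
  expect_identical(nrow(quantifySample(scans[0, ], panel)), 0L)

  # an analyte with no same-class standard is reported, not fatal
  scans2 <- rbind(scans, data.frame(lipid_name = rep("FFA(18:1)", 20),
                                    scan_index = 1:20, intensity = 50))
  out2 <- quantifySample(scans2, panel)
  bad <- out2[out2$lipid_name == "FFA(18:1)", ]
  expect_true(is.na(bad$concentration_nmol_per_g))
  expect_match(bad$note, "FFA")
  expect_equal(out2$concentration_nmol_per_g[out2$lipid_name == "PE(36:2)"], 10)
})

test_that("quantification is scale-invariant and linear in the analyte", {
  panel <- data.frame(standard_id = "PC-IS-1", lipid_name = "d9-PC(34:1)",
                      lipid_class = "PC", total_carbons = 34L,
                      total_double_bonds = 1L,
                      concentration_nmol_per_ml = 8,
                      stringsAsFactors = FALSE)
  set.seed(20)
  analyte <- rlnorm(20, log(300), 0.1)
  standard <- rlnorm(20, log(150), 0.1)
  mk <- function(a, s) data.frame(
    lipid_name = rep(c("PC(34:1)", "d9-PC(34:1)"), each = 20),
    scan_index = rep(1:20, 2), intensity = c(a, s))
  base <- quantifySample(mk(analyte, standard), panel)$concentration_nmol_per_g
  scaled <- quantifySample(mk(3.7 * analyte, 3.7 * standard),
                           panel)$concentration_nmol_per_g
  doubled <- quantifySample(mk(2 * analyte, standard),
                            panel)$concentration_nmol_per_g
  expect_equal(scaled, base, tolerance = 1e-12)
  expect_equal(doubled, 2 * base, tolerance = 1e-12)
})

test_that("noise-free synthetic scans recover the generator concentrations
           exactly", {
  st <- generateStudy(noiselessConfig(seed = 31L))
  conc <- quantifyStudy(st$scansB, st$isPanel, groups = st$groups)
  truth <- st$panel$base_conc[match(st$truthB$species_id,
                                    st$panel$species_id)]
  names(truth) <- st$truthB$lipid_name
  got <- abundance(conc)
  expect_false(anyNA(got))
  for (j in seq_len(ncol(got)))
    expect_equal(unname(got[, j]), unname(truth[rownames(got)]),
                 tolerance = 1e-8)
})

test_that("outlier scans are absorbed by the trimming step", {
  st <- generateStudy(noiselessConfig(seed = 8L, outlierScanRate = 0.05,
                                      outlierScanMagnitude = 5,
                                      scanNoiseCv = 0.01))
  conc <- quantifyStudy(st$scansB, st$isPanel)
  truth <- st$panel$base_conc[match(st$truthB$species_id,
                                    st$panel$species_id)]
  rel_err <- abs(sweep(abundance(conc), 1L,
                       truth[match(rownames(conc), st$truthB$lipid_name)],
                       "/") - 1)
  expect_lt(median(rel_err), 0.02)
})

test_that("scan tables and IS panels round-trip through CSV", {
  tmp <- withr::local_tempdir()
  st <- generateStudy(noiselessConfig(seed = 2L))
  scan_path <- file.path(tmp, "scans.csv")
  write.csv(st$scansB[1:800, ], scan_path, row.names = FALSE)
  expect_identical(nrow(readScanTable(scan_path)), 800L)

  panel_path <- file.path(tmp, "panel.csv")
  write.csv(st$isPanel[, c("standard_id", "lipid_name",
                           "concentration_nmol_per_ml")],
            panel_path, row.names = FALSE)
  panel <- readIsPanel(panel_path)
  expect_identical(panel$lipid_class, st$isPanel$lipid_class)
  expect_identical(panel$total_carbons, st$isPanel$total_carbons)
})
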