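# Welch tests, FDR adjustment, direction calls, class totals, consensus.

test_that("Welch's test matches stats::t.test to 1e-10 on random inputs", {
  set.seed(77)
  for (i in 1:120) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    ours <- welchTTest(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch's test agrees with the textbook formulas and handles
           degenerate groups", {
  x <- c(10, 11, 12, 13); y <- c(20, 21, 22, 23)
  ours <- welchTTest(x, y)
  ref <- oracleWelch(x, y)
  expect_equal(ours$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(ours$df, ref$df, tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p_value, tolerance = 1e-12)

  same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welchTTest(c(5, 5), c(7, 7)), class = "lipidInputError")
  expect_error(welchTTest(1, c(1, 2)), class = "lipidInputError")
})

test_that("row-wise Welch results equal per-row scalar tests", {
  set.seed(11)
  x <- matrix(rnorm(50, 10), nrow = 5)
  y <- matrix(rnorm(40, 12), nrow = 5)
  rw <- rowWelchTest(x, y)
  for (i in 1:5) {
    one <- welchTTest(x[i, ], y[i, ])
    expect_equal(rw$statistic[i], one$statistic, tolerance = 1e-12)
    expect_equal(rw$p_value[i], one$p_value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches a hand-stepped oracle and preserves
           order", {
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdrAdjust(0.031), 0.031)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(303)
  for (i in 1:100) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    q <- fdrAdjust(p)
    expect_equal(q, oracleBH(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_identical(order(q[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(fdrAdjust(c(0.5, 1.2)), class = "lipidInputError")
  expect_equal(fdrAdjust(c(0.01, NA, 0.5)), c(oracleBH(c(0.01, 0.5))[1], NA,
                                              oracleBH(c(0.01, 0.5))[2]))
})

test_that("direction calls are exhaustive and swap under group relabeling", {
  set.seed(21)
  n_lip <- 60L
  m <- matrix(rlnorm(n_lip * 20, log(100), 0.2), nrow = n_lip)
  m[1:20, 11:20] <- m[1:20, 11:20] * 0.4   # decreased in old
  m[21:25, 11:20] <- m[21:25, 11:20] * 2.5 # increased in old
  rownames(m) <- sprintf("L%03d", seq_len(n_lip))
  groups <- rep(c("young", "old"), each = 10)
  res <- differentialAnalysis(m, groups)
  cl <- classifyDeregulated(res)
  expect_identical(sum(cl$counts), n_lip)
  expect_gt(cl$counts[["decreased"]], 15L)
  expect_gt(cl$counts[["increased"]], 2L)
  # relabeling the groups swaps increased and decreased
  flipped <- classifyDeregulated(differentialAnalysis(m, rev(groups)))
  expect_identical(flipped$counts[["increased"]], cl$counts[["decreased"]])
  expect_identical(flipped$counts[["decreased"]], cl$counts[["increased"]])
  # no significant lipids: everything unchanged
  null_res <- res
  null_res$q_value <- pmax(null_res$q_value, 0.9)
  expect_identical(classifyDeregulated(null_res)$counts[["unchanged"]], n_lip)
})

test_that("significance includes q values exactly at the threshold", {
  res <- data.frame(q_value = c(0.049, 0.05, 0.051),
                    mean_young = c(1, 1, 1), mean_old = c(2, 2, 2))
  cl <- classifyDeregulated(res, fdr = 0.05)
  expect_identical(cl$results$significant, c(TRUE, TRUE, FALSE))
})

test_that("a planted 2-fold decrease in half the panel is detected with
           high sensitivity", {
  set.seed(99)
  n_lip <- 1000
  m <- matrix(rlnorm(n_lip * 20, log(100), sqrt(log1p(0.2^2))), nrow = n_lip)
  hit <- seq_len(n_lip / 2)
  m[hit, 11:20] <- m[hit, 11:20] * 0.5
  res <- differentialAnalysis(m, rep(c("young", "old"), each = 10))
  sens <- mean(res$direction[hit] == "decreased")
  expect_gt(sens, 0.9)
})

test_that("class totals reproduce a planted class-specific decrease", {
  st <- generateStudy(smallConfig(seed = 15L, effectFraction = 0.3,
                                  effectIncreaseFraction = 0))
  conc <- quantifyStudy(st$scansB, st$isPanel, groups = st$groups)
  ct <- classTotalsTest(conc, groups = st$groups[colnames(conc)])
  expect_true("TOTAL" %in% ct$lipid_class)
  # effects are concentrated in TAG by construction
  expect_lt(ct$p_value[ct$lipid_class == "TAG"], 0.05)
  # a one-class panel collapses to the global test
  one <- classTotalsTest(matrix(rlnorm(40, 3, 0.1), nrow = 4),
                         classes = rep("PC", 4),
                         groups = rep(c("young", "old"), each = 5))
  expect_equal(one$p_value[one$lipid_class == "PC"],
               one$p_value[one$lipid_class == "TOTAL"])
  expect_error(classTotalsTest(matrix(1:8, 2), classes = c("PC", NA),
                               groups = rep(c("young", "old"), each = 2)),
               class = "lipidInputError")
})

test_that("class totals are null-distributed under permuted group labels", {
  set.seed(55)
  m <- matrix(rlnorm(30 * 20, log(50), 0.3), nrow = 30)
  classes <- rep(c("PC", "TAG", "PE"), each = 10)
  hits <- replicate(200, {
    g <- sample(rep(c("young", "old"), each = 10))
    ct <- classTotalsTest(m, classes, g)
    ct$p_value[ct$lipid_class == "TOTAL"] < 0.05
  })
  expect_lt(mean(hits), 0.12)
})

test_that("cross-platform consensus requires shared annotation, shared
           significance and matching direction", {
  mk <- function(ann, cls, sig, dir) data.frame(
    annotation = ann, lipid_class = cls, significant = sig, direction = dir,
    stringsAsFactors = FALSE)
  a <- mk(c("PC(34:1)", "PE(36:2)", "SM(20:0)", "TAG50:1-FA16:0"),
          c("PC", "PE", "SM", "TAG"),
          c(TRUE, TRUE, TRUE, TRUE),
          c("decreased", "decreased", "increased", "decreased"))
  b <- mk(c("PC(34:1)", "PE(36:2)", "CE(18:2)"),
          c("PC", "PE", "CE"),
          c(TRUE, TRUE, TRUE),
          c("decreased", "increased", "decreased"))
  out <- crossPlatformConsensus(a, b)
  expect_identical(out$shared_same_direction$annotation, "PC(34:1)")
  expect_identical(out$discordant$annotation, "PE(36:2)")
  expect_identical(out$n_deregulated_a, 3L)  # TAG excluded
  expect_identical(out$n_deregulated_b, 3L)
  # identical result sets share everything
  self <- crossPlatformConsensus(a, a)
  expect_identical(nrow(self$shared_same_direction), 3L)
  # disjoint panels share nothing
  disj <- crossPlatformConsensus(a, mk("LPC(18:0)", "LPC", TRUE, "decreased"))
  expect_identical(nrow(disj$shared_same_direction), 0L)
})
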