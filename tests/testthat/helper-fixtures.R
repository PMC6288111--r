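# Shared fixtures: a small, fast study configuration and independent
# oracles used to cross-check the package's statistics.

smallPanel <- c(TAG = 12L, PC = 8L, DAG = 4L, PE = 5L, PI = 3L, LPC = 4L,
                LPE = 3L, SM = 5L, CER = 4L, CE = 5L, FFA = 4L)

smallConfig <- function(seed = 42L, ...) {
  simulationConfig(seed = seed, nYoung = 8L, nOld = 8L, panel = smallPanel,
                   ...)
}

# a noise-free configuration: platform observations equal the ground truth;
# any default can still be overridden through ...
noiselessConfig <- function(seed = 42L, ...) {
  args <- list(seed = seed, speciesLogSd = 0.5, bioLogSd = 0,
               effectFraction = 0, noiseCvA = 0, noiseCvB = 0,
               sampleScaleCv = 0, missingRate = 0, nLowPresence = 0L,
               scanNoiseCv = 0, outlierScanRate = 0, calibrationNoiseCv = 0,
               intradayCv = 0, interdayCv = 0, saturationHalfFactor = Inf)
  over <- list(...)
  args[names(over)] <- over
  do.call(smallConfig, args)
}

# Brute-force oracle for the 20-scan trimming rule: rank scans by absolute
# deviation from the median, ties broken by larger intensity then scan
# order, drop the worst four, average the rest.
oracleTrimmedMean <- function(x) {
  stopifnot(length(x) == 20L)
  d <- data.frame(i = seq_along(x), x = x, dev = abs(x - median(x)))
  d <- d[order(-d$dev, -d$x, d$i), ]
  mean(d$x[-(1:4)])
}

# Hand-stepped Benjamini-Hochberg adjustment (step-up with enforced
# monotonicity), independent of stats::p.adjust.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Welch's t-test from the textbook formulas.
oracleWelch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}
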