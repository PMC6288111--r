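# Synthetic paired-platform lipidomics studies with known ground truth.
# The generator emulates the structure of a two-platform plasma aging study:
# a lipid panel dominated by TAG and PC, lognormal abundances and
# multiplicative platform noise, an aging effect that decreases roughly half
# of the lipids (concentrated in TAG), signal saturation at high
# concentration for TAG/DAG/CE/CER on the targeted platform, spiked internal
# standards on both platforms, replicate injections across days, 7-point IS
# dilution series, and 20-scan MRM intensity sets containing outlier scans.

.DEFAULT_PANEL <- c(TAG = 100L, PC = 60L, DAG = 15L, PE = 25L, PI = 15L,
                    LPC = 20L, LPE = 10L, SM = 25L, CER = 15L, CE = 20L,
                    FFA = 15L)

.DEFAULT_CONC <- c(TAG = 20, PC = 50, DAG = 2, PE = 5, PI = 3, LPC = 30,
                   LPE = 2, SM = 20, CER = 1, CE = 100, FFA = 50)

# per-class coverage probabilities: P(shared), P(A only), P(B only).
# PI and ether-PC are untargeted-only; FFA and most CE targeted-only.
.DEFAULT_COVERAGE <- list(
  TAG = c(0.70, 0.15, 0.15), PC = c(0.60, 0.30, 0.10),
  DAG = c(0.70, 0.15, 0.15), PE = c(0.70, 0.15, 0.15),
  PI = c(0, 1, 0), LPC = c(0.70, 0.15, 0.15), LPE = c(0.70, 0.15, 0.15),
  SM = c(0.70, 0.15, 0.15), CER = c(0.70, 0.15, 0.15),
  CE = c(0.20, 0, 0.80), FFA = c(0, 0, 1))

# number of deuterated standards per covered class (54 in total; the
# targeted platform's panel spans 10 classes, PI is not covered)
.DEFAULT_IS_COUNTS <- c(TAG = 10L, PC = 8L, PE = 6L, DAG = 4L, LPC = 4L,
                        LPE = 4L, SM = 6L, CER = 4L, CE = 4L, FFA = 4L)

#' Configuration of a synthetic paired-platform study
#'
#' Collects every generator parameter with defaults chosen to emulate a
#' two-platform mouse plasma aging study; the same configuration object
#' drives [generateStudy()], [generateNameList()] and
#' [generateDilutionSeries()], and the seed fully determines their output.
#'
#' @param seed integer RNG seed.
#' @param nYoung,nOld biological sample count per group (default 10 + 10).
#' @param panel named integer vector: species per lipid class; the default
#'   (~320 species) is dominated by TAG and PC, mirroring their prevalence
#'   in plasma.
#' @param nLipids optional total panel size; when given, the default class
#'   composition is rescaled proportionally to this many species.
#' @param classConcMedian named vector of class-typical concentrations
#'   (nmol/g), also the recommended IS spike levels.
#' @param speciesLogSd log-sd of species baseline abundances within a class.
#' @param bioLogSd log-sd of per-sample biological variation (0.2 is about a
#'   20\% within-group CV).
#' @param effectFraction fraction of the panel with a true age effect.
#' @param effectFoldChange old/young fold change for affected lipids
#'   (default 0.5, a 2-fold decrease).
#' @param effectIncreaseFraction fraction of affected lipids that increase
#'   instead (small; most species decrease with age).
#' @param crossPlatformRho target correlation of the two platforms'
#'   error-free biological signals; the age effect itself is shared.
#' @param noiseCvA,noiseCvB multiplicative injection-level measurement noise
#'   (CV) per platform, matching the injected intra-day precision.
#' @param sampleScaleCv CV of per-sample injection/extraction scale factors
#'   on the untargeted platform (removed by IS normalization).
#' @param missingRate probability that an untargeted measurement is missing.
#' @param nLowPresence untargeted features planted at <= 50\% presence
#'   (exercise the presence filter).
#' @param nBlankOnly planted blank-dominated contaminant features.
#' @param nBlankSamples solvent blank injections.
#' @param adductDuplicateRate probability that an identified feature also
#'   appears as a minor second adduct.
#' @param saturatingClasses classes whose targeted-platform response
#'   saturates at high concentration.
#' @param saturationHalfFactor half-saturation concentration as a multiple
#'   of the class recommended level (`Inf` disables saturation).
#' @param ladder 7 dilution factors relative to the recommended level,
#'   spanning more than 2 orders of magnitude.
#' @param calibrationNoiseCv measurement noise on dilution-series responses.
#' @param scansPerLipid MRM scans per lipid (fixed at 20).
#' @param scanNoiseCv scan-to-scan jitter within a scan set.
#' @param outlierScanRate,outlierScanMagnitude probability and multiplicative
#'   size of outlier scans.
#' @param intradayCv,interdayCv injection noise and day-effect CV for the
#'   replicate-injection sets (5 replicates x 3 days).
#' @return An object of class `"SimulationConfig"` (a validated list).
#' @export
simulationConfig <- function(seed = 1L, nYoung = 10L, nOld = 10L,
                             panel = NULL, nLipids = NULL,
                             classConcMedian = .DEFAULT_CONC,
                             speciesLogSd = 1.0, bioLogSd = 0.2,
                             effectFraction = 0.5, effectFoldChange = 0.5,
                             effectIncreaseFraction = 0.05,
                             crossPlatformRho = 0.7,
                             noiseCvA = 0.05, noiseCvB = 0.05,
                             sampleScaleCv = 0.15, missingRate = 0.02,
                             nLowPresence = 12L, nBlankOnly = 10L,
                             nBlankSamples = 2L, adductDuplicateRate = 0.3,
                             saturatingClasses = c("TAG", "DAG", "CE", "CER"),
                             saturationHalfFactor = 4,
                             ladder = c(0.08, 0.2, 0.5, 1, 2.5, 6.3, 16),
                             calibrationNoiseCv = 0.05,
                             scansPerLipid = 20L, scanNoiseCv = 0.02,
                             outlierScanRate = 0.05,
                             outlierScanMagnitude = 5,
                             intradayCv = 0.05, interdayCv = 0.05) {
  if (is.null(panel)) {
    panel <- .DEFAULT_PANEL
    if (!is.null(nLipids)) panel <- .scale_panel(panel, as.integer(nLipids))
  }
  cfg <- list(seed = as.integer(seed), nYoung = as.integer(nYoung),
              nOld = as.integer(nOld), panel = panel,
              classConcMedian = classConcMedian,
              speciesLogSd = speciesLogSd, bioLogSd = bioLogSd,
              effectFraction = effectFraction,
              effectFoldChange = effectFoldChange,
              effectIncreaseFraction = effectIncreaseFraction,
              crossPlatformRho = crossPlatformRho,
              noiseCvA = noiseCvA, noiseCvB = noiseCvB,
              sampleScaleCv = sampleScaleCv, missingRate = missingRate,
              nLowPresence = as.integer(nLowPresence),
              nBlankOnly = as.integer(nBlankOnly),
              nBlankSamples = as.integer(nBlankSamples),
              adductDuplicateRate = adductDuplicateRate,
              saturatingClasses = saturatingClasses,
              saturationHalfFactor = saturationHalfFactor,
              ladder = ladder, calibrationNoiseCv = calibrationNoiseCv,
              scansPerLipid = as.integer(scansPerLipid),
              scanNoiseCv = scanNoiseCv,
              outlierScanRate = outlierScanRate,
              outlierScanMagnitude = outlierScanMagnitude,
              intradayCv = intradayCv, interdayCv = interdayCv)
  class(cfg) <- "SimulationConfig"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (nYoung < 1L || nOld < 1L) .input_error("sample counts must be >= 1")
    if (any(panel < 0L) || sum(panel) < 1L)
      .input_error("the panel needs at least one species")
    if (!all(names(panel) %in% names(.DEFAULT_CONC)))
      .input_error("panel classes must be known lipid classes")
    if (effectFraction < 0 || effectFraction > 1)
      .input_error("effectFraction must lie in [0, 1]")
    if (crossPlatformRho < 0 || crossPlatformRho > 1)
      .input_error("crossPlatformRho must lie in [0, 1]")
    if (any(c(noiseCvA, noiseCvB, bioLogSd, speciesLogSd, sampleScaleCv,
              scanNoiseCv, calibrationNoiseCv, intradayCv, interdayCv) < 0))
      .input_error("noise parameters must be non-negative")
    if (length(ladder) != 7L)
      .input_error("the dilution ladder must have exactly 7 points")
    if (is.unsorted(ladder, strictly = TRUE))
      .input_error("dilution ladder must be strictly increasing")
    if (max(ladder) / min(ladder) <= 100)
      .input_error("dilution ladder must span more than 2 orders of magnitude")
    if (scansPerLipid != 20L)
      .input_error("the targeted platform collects exactly 20 scans per lipid")
  })
  invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(
    "SimulationConfig: %d lipids (%s), %d + %d samples, seed %d\n",
    sum(x$panel),
    paste(sprintf("%s=%d", names(x$panel), x$panel), collapse = " "),
    x$nYoung, x$nOld, x$seed))
  invisible(x)
}

.scale_panel <- function(panel, n) {
  raw <- panel * n / sum(panel)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0L) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(out), names(panel))
}

.rint <- function(a, b) if (a >= b) as.integer(a) else sample(seq.int(a, b), 1L)

# partition a TAG sum composition into three chains (12-26 C, 0-6 db each)
.tag_chains <- function(C, D) {
  c1 <- .rint(max(12L, C - 52L), min(26L, C - 24L))
  c2 <- .rint(max(12L, C - c1 - 26L), min(26L, C - c1 - 12L))
  c3 <- C - c1 - c2
  d1 <- .rint(max(0L, D - 12L), min(6L, D))
  d2 <- .rint(max(0L, D - d1 - 6L), min(6L, D - d1))
  d3 <- D - d1 - d2
  data.frame(c = c(c1, c2, c3), d = c(d1, d2, d3))
}

.chain_token <- function(c, d, ether = "") {
  sprintf("%s%d:%d", ifelse(nzchar(ether), paste0(ether, "-"), ""), c, d)
}

# Build the species panel with names for both platforms and all ground-truth
# bookkeeping. Must be called inside a seeded block.
.build_panel <- function(cfg) {
  pieces <- list()
  pair_chain_pool <- expand.grid(c = c(14L, 15L, 16L, 17L, 18L, 20L, 22L),
                                 d = 0:4)
  pair_pool <- expand.grid(i = seq_len(nrow(pair_chain_pool)),
                           j = seq_len(nrow(pair_chain_pool)))
  pair_pool <- pair_pool[pair_pool$i <= pair_pool$j, , drop = FALSE]
  # order pairs so i indexes the lexicographically smaller chain
  pp <- pair_chain_pool
  swap <- pp$c[pair_pool$i] > pp$c[pair_pool$j] |
    (pp$c[pair_pool$i] == pp$c[pair_pool$j] &
       pp$d[pair_pool$i] > pp$d[pair_pool$j])
  tmp <- pair_pool$i[swap]; pair_pool$i[swap] <- pair_pool$j[swap]
  pair_pool$j[swap] <- tmp
  single_pool <- expand.grid(c = 14:26, d = 0:6)
  sphingo_pool <- expand.grid(c = 12:34, d = 0:3)
  tag_pool <- expand.grid(c = 40:70, d = 0:11)

  for (cls in names(cfg$panel)) {
    n <- cfg$panel[[cls]]
    if (n == 0L) next
    cover_p <- .DEFAULT_COVERAGE[[cls]]
    coverage <- sample(c("both", "a_only", "b_only"), n, replace = TRUE,
                       prob = cover_p)

    if (cls == "TAG") {
      if (n > nrow(tag_pool))
        .input_error("TAG panel larger than the distinct sum-composition pool")
      sums <- tag_pool[sample.int(nrow(tag_pool), n), , drop = FALSE]
      rows <- lapply(seq_len(n), function(k) {
        ch <- .tag_chains(sums$c[k], sums$d[k])
        name_a <- sprintf("TAG(%s)", paste(.chain_token(ch$c, ch$d),
                                           collapse = "/"))
        distinct <- ch[!duplicated(paste(ch$c, ch$d)), , drop = FALSE]
        ann <- sprintf("TAG%d:%d-FA%d:%d", sums$c[k], sums$d[k],
                       distinct$c, distinct$d)
        data.frame(lipid_class = cls, name_a = name_a,
                   name_b = ann[1L], annotations = paste(ann, collapse = ";"),
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
    } else if (cls %in% c("PC", "PE", "PI", "DAG")) {
      if (n > nrow(pair_pool))
        .input_error(sprintf("%s panel larger than the chain-pair pool", cls))
      sel <- pair_pool[sample.int(nrow(pair_pool), n), , drop = FALSE]
      c1 <- pp$c[sel$i]; d1 <- pp$d[sel$i]
      c2 <- pp$c[sel$j]; d2 <- pp$d[sel$j]
      ether <- rep("", n)
      if (cls == "PC") {
        # half of the untargeted-only PC are ether-linked (plasmalogen-like);
        # only strict pairs take the prefix so chain order stays canonical
        cand <- which(coverage == "a_only" & (c1 < c2 | d1 < d2))
        ether[cand[seq_len(floor(length(cand) / 2))]] <- "O"
      }
      t1 <- .chain_token(c1, d1, ether); t2 <- .chain_token(c2, d2)
      canon <- sprintf("%s(%s/%s)", cls, t1, t2)
      df <- data.frame(lipid_class = cls,
                       name_a = canon,
                       name_b = sprintf("%s(%s/%s)", cls, t2, t1),
                       annotations = canon, stringsAsFactors = FALSE)
    } else if (cls %in% c("SM", "CER")) {
      if (n > nrow(sphingo_pool))
        .input_error(sprintf("%s panel larger than the N-acyl pool", cls))
      sel <- sphingo_pool[sample.int(nrow(sphingo_pool), n), , drop = FALSE]
      canon <- sprintf("%s(%d:%d)", cls, sel$c, sel$d)
      df <- data.frame(lipid_class = cls,
                       name_a = sprintf("%s(d%d:%d)", cls, sel$c + 18L,
                                        sel$d + 1L),
                       name_b = canon, annotations = canon,
                       stringsAsFactors = FALSE)
    } else {
      if (n > nrow(single_pool))
        .input_error(sprintf("%s panel larger than the composition pool", cls))
      sel <- single_pool[sample.int(nrow(single_pool), n), , drop = FALSE]
      canon <- sprintf("%s(%d:%d)", cls, sel$c, sel$d)
      df <- data.frame(lipid_class = cls, name_a = canon, name_b = canon,
                       annotations = canon, stringsAsFactors = FALSE)
    }
    df$coverage <- coverage
    pieces[[cls]] <- df
  }
  panel <- do.call(rbind, pieces)
  rownames(panel) <- NULL
  panel$species_id <- sprintf("L%04d", seq_len(nrow(panel)))

  med <- cfg$classConcMedian[panel$lipid_class]
  panel$base_conc <- med * exp(stats::rnorm(nrow(panel), 0, cfg$speciesLogSd))

  # age effects: TAG first, then a random draw from the rest, so the
  # deregulated set is concentrated in TAG as in aging plasma
  n_eff <- round(cfg$effectFraction * nrow(panel))
  tag_idx <- which(panel$lipid_class == "TAG")
  other_idx <- sample(which(panel$lipid_class != "TAG"))
  eff_idx <- c(sample(tag_idx), other_idx)[seq_len(n_eff)]
  panel$affected <- seq_len(nrow(panel)) %in% eff_idx
  up <- rep(FALSE, nrow(panel))
  up[eff_idx] <- stats::runif(length(eff_idx)) < cfg$effectIncreaseFraction
  panel$fold <- ifelse(!panel$affected, 1,
                       ifelse(up, 1 / cfg$effectFoldChange,
                              cfg$effectFoldChange))
  panel$direction_true <- ifelse(!panel$affected, "unchanged",
                                 ifelse(up, "increased", "decreased"))
  panel
}

# hyperbolic saturating response on the concentration axis; half = Inf is
# the linear limit
.saturate <- function(x, half) {
  if (!is.finite(half)) return(x)
  x / (1 + x / half)
}

.class_half <- function(cls, cfg) {
  ifelse(cls %in% cfg$saturatingClasses,
         cfg$saturationHalfFactor * cfg$classConcMedian[cls], Inf)
}

# deuterated IS panel: standards spread over each class's composition range
.build_is_panel <- function(cfg, panel) {
  counts <- .DEFAULT_IS_COUNTS[names(.DEFAULT_IS_COUNTS) %in%
                                 names(cfg$panel)]
  rows <- list()
  for (cls in names(counts)) {
    k <- counts[[cls]]
    carb_range <- switch(cls,
      TAG = c(42L, 60L), PC = c(30L, 40L), PE = c(30L, 40L),
      DAG = c(30L, 40L), LPC = c(14L, 24L), LPE = c(14L, 24L),
      SM = c(14L, 26L), CER = c(14L, 26L), CE = c(14L, 24L),
      FFA = c(14L, 24L))
    carbons <- unique(round(seq(carb_range[1L], carb_range[2L],
                                length.out = k)))
    while (length(carbons) < k) carbons <- c(carbons, max(carbons) + 1L)
    db <- rep_len(c(0L, 1L, 2L), k)
    name <- sprintf("d9-%s(%d:%d)", cls, carbons, db)
    rows[[cls]] <- data.frame(
      standard_id = sprintf("%s-IS-%02d", cls, seq_len(k)),
      lipid_name = name, lipid_class = cls,
      total_carbons = as.integer(carbons), total_double_bonds = db,
      concentration_nmol_per_ml = unname(cfg$classConcMedian[cls]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# long-format scan sets for a response matrix (rows x samples): each cell
# becomes 20 scans jittered around its response with outlier scans injected
.scan_long <- function(resp, row_names, cfg) {
  n_row <- nrow(resp); n_samp <- ncol(resp); n_scan <- cfg$scansPerLipid
  n_cell <- n_row * n_samp
  base <- rep(as.vector(resp), each = n_scan)
  scan <- base * .lnoise(n_cell * n_scan, cfg$scanNoiseCv)
  if (cfg$outlierScanRate > 0) {
    out_mask <- stats::runif(n_cell * n_scan) < cfg$outlierScanRate
    scan[out_mask] <- scan[out_mask] * cfg$outlierScanMagnitude
  }
  data.frame(
    sample_id = rep(colnames(resp), each = n_scan * n_row),
    lipid_name = rep(rep(row_names, each = n_scan), times = n_samp),
    q1 = rep(rep(round(500 + seq_len(n_row) * 0.7, 1), each = n_scan),
             times = n_samp),
    q3 = rep(rep(round(180 + seq_len(n_row) * 0.3, 1), each = n_scan),
             times = n_samp),
    scan_index = rep(seq_len(n_scan), times = n_cell),
    intensity = scan, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic paired-platform study
#'
#' Draws a lipid panel, ground-truth concentrations and every raw artifact
#' both platform pipelines consume: the untargeted feature table (with
#' spiked IS features, solvent blanks, adduct duplicates, missing values and
#' planted blank-only contaminants), the targeted platform's MRM scan table
#' and IS panel, replicate-injection sets, and per-IS calibration/dilution
#' series. The same seed gives bit-identical output.
#'
#' @param config a [simulationConfig()] object.
#' @return An object of class `"SyntheticStudy"`: list with elements
#'   `config`, `panel` (per-species ground truth), `truthA`/`truthB`
#'   (per-measured-row truth), `platformA` ([LipidomicsExperiment-class]
#'   feature table), `isFeatures` (the two spiked IS feature ids), `scansB`
#'   (long MRM scan table), `isPanel`, `replicates`, `calibrationB`,
#'   `dilutionA`, `groups` (named sample-to-group vector) and `expected`
#'   (planted coverage overlap bookkeeping).
#' @export
generateStudy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .validate_config(config)
  cfg <- config
  .with_seed(cfg$seed, {
    panel <- .build_panel(cfg)
    nsp <- nrow(panel)
    n_bio <- cfg$nYoung + cfg$nOld
    samples <- sprintf("S%02d", seq_len(n_bio))
    group <- stats::setNames(rep(c("young", "old"), c(cfg$nYoung, cfg$nOld)),
                             samples)

    # error-free per-platform biological signals: shared age effect, shared
    # biological deviation at correlation rho, platform-specific remainder
    rho <- cfg$crossPlatformRho
    z <- matrix(stats::rnorm(nsp * n_bio), nsp, n_bio)
    ua <- matrix(stats::rnorm(nsp * n_bio), nsp, n_bio)
    ub <- matrix(stats::rnorm(nsp * n_bio), nsp, n_bio)
    dev_a <- cfg$bioLogSd * (sqrt(rho) * z + sqrt(1 - rho) * ua)
    dev_b <- cfg$bioLogSd * (sqrt(rho) * z + sqrt(1 - rho) * ub)
    foldfac <- outer(panel$fold, as.integer(group == "old"), `^`)
    signal_a <- panel$base_conc * foldfac * exp(dev_a)
    signal_b <- panel$base_conc * foldfac * exp(dev_b)
    colnames(signal_a) <- colnames(signal_b) <- samples

    ## ---- platform A: untargeted feature table -------------------------
    a_idx <- which(panel$coverage %in% c("both", "a_only"))
    resp_factor <- exp(stats::rnorm(length(a_idx), log(1e5), 0.8)) /
      cfg$classConcMedian[panel$lipid_class[a_idx]]
    scale <- .lnoise(n_bio, cfg$sampleScaleCv)
    int_a <- signal_a[a_idx, , drop = FALSE] * resp_factor *
      rep(scale, each = length(a_idx)) *
      matrix(.lnoise(length(a_idx) * n_bio, cfg$noiseCvA),
             nrow = length(a_idx))

    # missingness + planted low-presence features
    miss <- matrix(stats::runif(length(int_a)) < cfg$missingRate,
                   nrow = nrow(int_a))
    low_idx <- integer(0)
    if (cfg$nLowPresence > 0L && length(a_idx) > cfg$nLowPresence) {
      low_idx <- sample(seq_along(a_idx), cfg$nLowPresence)
      for (i in low_idx) {
        hide <- sample(n_bio, ceiling(0.6 * n_bio))
        miss[i, hide] <- TRUE
      }
    }
    int_a[miss] <- NA_real_

    blanks <- if (cfg$nBlankSamples > 0L)
      sprintf("B%02d", seq_len(cfg$nBlankSamples)) else character(0)
    blank_a <- matrix(0, nrow(int_a), length(blanks),
                      dimnames = list(NULL, blanks))

    feat <- data.frame(
      feature_id = sprintf("F%04d", seq_along(a_idx)),
      mz = round(400 + seq_along(a_idx) * 1.37, 4),
      rt = round(60 + seq_along(a_idx) * 2.1, 1),
      adduct = "[M+H]+",
      lipid_name = panel$name_a[a_idx],
      species_id = panel$species_id[a_idx],
      stringsAsFactors = FALSE)
    mat <- cbind(int_a, blank_a)

    # minor second adducts for a fraction of identified features
    dup <- which(stats::runif(length(a_idx)) < cfg$adductDuplicateRate)
    if (length(dup)) {
      dup_mat <- mat[dup, , drop = FALSE] * 0.12 *
        matrix(.lnoise(length(dup) * ncol(mat), cfg$noiseCvA),
               nrow = length(dup))
      dup_feat <- feat[dup, , drop = FALSE]
      dup_feat$feature_id <- sprintf("F%04dNa", dup)
      dup_feat$adduct <- "[M+Na]+"
      dup_feat$mz <- dup_feat$mz + 21.9819
      mat <- rbind(mat, dup_mat)
      feat <- rbind(feat, dup_feat)
    }

    # blank-dominated contaminant features
    if (cfg$nBlankOnly > 0L) {
      bl_int <- exp(stats::rnorm(cfg$nBlankOnly, log(5e4), 0.5))
      bl_mat <- cbind(
        matrix(bl_int * 0.02, cfg$nBlankOnly, n_bio) *
          matrix(.lnoise(cfg$nBlankOnly * n_bio, cfg$noiseCvA),
                 nrow = cfg$nBlankOnly),
        matrix(bl_int, cfg$nBlankOnly, length(blanks)))
      bl_feat <- data.frame(
        feature_id = sprintf("BLK%03d", seq_len(cfg$nBlankOnly)),
        mz = round(300 + seq_len(cfg$nBlankOnly) * 3.11, 4),
        rt = round(30 + seq_len(cfg$nBlankOnly) * 1.7, 1),
        adduct = "[M+H]+", lipid_name = NA_character_,
        species_id = NA_character_, stringsAsFactors = FALSE)
      mat <- rbind(mat, bl_mat)
      feat <- rbind(feat, bl_feat)
    }

    # the two spiked IS features (present everywhere, tracking the
    # per-sample scale factors)
    is_feat_ids <- c("IS_PC", "IS_TAG")
    is_base <- c(1.2e5, 8e4)
    is_mat <- rbind(
      is_base[1L] * c(scale * .lnoise(n_bio, cfg$noiseCvA),
                      rep(1, length(blanks))),
      is_base[2L] * c(scale * .lnoise(n_bio, cfg$noiseCvA),
                      rep(1, length(blanks))))
    is_feat <- data.frame(
      feature_id = is_feat_ids, mz = c(720.55, 860.77), rt = c(310.0, 1205.0),
      adduct = "[M+H]+",
      lipid_name = c("PC(17:0/14:1)", "d5-TAG(17:0/17:0/17:1)"),
      species_id = NA_character_, stringsAsFactors = FALSE)
    mat <- rbind(mat, is_mat)
    feat <- rbind(feat, is_feat)
    rownames(mat) <- feat$feature_id

    col_data <- data.frame(
      sample_id = c(samples, blanks),
      role = c(rep("biological", n_bio), rep("blank", length(blanks))),
      group = c(unname(group), rep(NA_character_, length(blanks))),
      stringsAsFactors = FALSE)
    platformA <- LipidomicsExperiment(mat, rowData = feat,
                                      colData = col_data,
                                      units = "intensity",
                                      platform = "untargeted LC-MS")

    truthA <- data.frame(
      feature_id = feat$feature_id, species_id = feat$species_id,
      stringsAsFactors = FALSE)
    truthA <- merge(truthA,
                    panel[, c("species_id", "lipid_class", "annotations",
                              "affected", "direction_true")],
                    by = "species_id", all.x = TRUE, sort = FALSE)
    truthA$low_presence <- truthA$feature_id %in%
      sprintf("F%04d", low_idx)

    ## ---- platform B: MRM scan sets + IS panel -------------------------
    b_species <- which(panel$coverage %in% c("both", "b_only"))
    b_rows <- do.call(rbind, lapply(b_species, function(i) {
      anns <- strsplit(panel$annotations[i], ";", fixed = TRUE)[[1]]
      nm <- if (panel$lipid_class[i] == "TAG") anns else panel$name_b[i]
      data.frame(species = i, row_name = nm,
                 lipid_class = panel$lipid_class[i], stringsAsFactors = FALSE)
    }))
    half_b <- .class_half(b_rows$lipid_class, cfg)
    slope <- 1000
    conc_obs <- signal_b[b_rows$species, , drop = FALSE] *
      matrix(.lnoise(nrow(b_rows) * n_bio, cfg$noiseCvB), nrow = nrow(b_rows))
    resp_b <- slope * .saturate_mat(conc_obs, half_b)
    rownames(resp_b) <- b_rows$row_name

    is_panel <- .build_is_panel(cfg, panel)
    half_is <- .class_half(is_panel$lipid_class, cfg)
    is_conc <- matrix(is_panel$concentration_nmol_per_ml, nrow(is_panel),
                      n_bio) *
      matrix(.lnoise(nrow(is_panel) * n_bio, cfg$noiseCvB),
             nrow = nrow(is_panel))
    resp_is <- slope * .saturate_mat(is_conc, half_is)
    rownames(resp_is) <- is_panel$lipid_name
    resp_all <- rbind(resp_b, resp_is)
    colnames(resp_all) <- samples
    scansB <- .scan_long(resp_all, rownames(resp_all), cfg)

    truthB <- data.frame(
      lipid_name = b_rows$row_name,
      species_id = panel$species_id[b_rows$species],
      lipid_class = b_rows$lipid_class,
      affected = panel$affected[b_rows$species],
      direction_true = panel$direction_true[b_rows$species],
      stringsAsFactors = FALSE)

    ## ---- replicate injections (5 x 3 days) ----------------------------
    analytes <- ifelse(panel$coverage == "a_only", panel$name_a, panel$name_b)
    n_day <- 3L; n_rep <- 5L
    day_eff <- matrix(.lnoise(nsp * n_day, cfg$interdayCv), nsp, n_day)
    reps <- data.frame(
      analyte = rep(analytes, each = n_day * n_rep),
      day = rep(rep(seq_len(n_day), each = n_rep), times = nsp),
      replicate = rep(seq_len(n_rep), times = n_day * nsp),
      stringsAsFactors = FALSE)
    reps$value <- rep(panel$base_conc, each = n_day * n_rep) *
      day_eff[cbind(rep(seq_len(nsp), each = n_day * n_rep), reps$day)] *
      .lnoise(nrow(reps), cfg$intradayCv)

    ## ---- IS dilution series (both platforms) --------------------------
    cal <- .build_dilution(cfg, is_panel)

    expected <- .expected_overlap(panel)
    out <- list(config = cfg, panel = panel, truthA = truthA, truthB = truthB,
                platformA = platformA, isFeatures = is_feat_ids,
                scansB = scansB, isPanel = is_panel, replicates = reps,
                calibrationB = cal$platform_b, dilutionA = cal$platform_a,
                groups = group, expected = expected)
    class(out) <- "SyntheticStudy"
    out
  })
}

.saturate_mat <- function(x, half) {
  # half recycles along rows
  x / (1 + x / half)
}

.build_dilution <- function(cfg, is_panel) {
  n_is <- nrow(is_panel)
  n_pt <- length(cfg$ladder)
  nominal <- rep(is_panel$concentration_nmol_per_ml, each = n_pt) *
    rep(cfg$ladder, times = n_is)
  half <- rep(.class_half(is_panel$lipid_class, cfg), each = n_pt)
  resp_b <- 1000 * (nominal / (1 + nominal / half)) *
    .lnoise(n_is * n_pt, cfg$calibrationNoiseCv)
  resp_a <- 50 * nominal * .lnoise(n_is * n_pt, cfg$calibrationNoiseCv)
  template <- data.frame(
    standard_id = rep(is_panel$standard_id, each = n_pt),
    lipid_class = rep(is_panel$lipid_class, each = n_pt),
    nominal = nominal,
    recommended = rep(cfg$ladder == 1, times = n_is),
    stringsAsFactors = FALSE)
  list(platform_a = cbind(template, response = resp_a),
       platform_b = cbind(template, response = resp_b))
}

.expected_overlap <- function(panel) {
  ann_list <- strsplit(panel$annotations, ";", fixed = TRUE)
  ann_a <- unlist(ann_list[panel$coverage %in% c("both", "a_only")])
  ann_b <- unlist(ann_list[panel$coverage %in% c("both", "b_only")])
  shared <- unlist(ann_list[panel$coverage == "both"])
  list(annotations_a = ann_a, annotations_b = ann_b, shared = shared,
       n_a = length(ann_a), n_b = length(ann_b), n_shared = length(shared),
       n_union = length(ann_a) + length(ann_b) - length(shared))
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf(
    "SyntheticStudy: %d species (%d untargeted features, %d targeted rows), %d + %d samples, seed %d\n",
    nrow(x$panel), nrow(x$platformA), length(unique(x$truthB$lipid_name)),
    x$config$nYoung, x$config$nOld, x$config$seed))
  invisible(x)
}

#' Generate paired platform name lists with a planted overlap
#'
#' Builds only the identification lists of a synthetic study: untargeted
#' names at the chain/sum level (including ether-linked PC and d-prefixed
#' SM/CER) and targeted names at the reporting level (including FFA and CE
#' unique to that platform), with the true overlap known by construction.
#'
#' @param config a [simulationConfig()] object.
#' @return list with `platform_a`, `platform_b` (character name vectors) and
#'   `expected` (planted annotation sets and counts).
#' @export
generateNameList <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .with_seed(config$seed, {
    panel <- .build_panel(config)
    a <- panel$coverage %in% c("both", "a_only")
    b <- panel$coverage %in% c("both", "b_only")
    names_b <- unlist(lapply(which(b), function(i) {
      if (panel$lipid_class[i] == "TAG")
        strsplit(panel$annotations[i], ";", fixed = TRUE)[[1]]
      else panel$name_b[i]
    }))
    list(platform_a = panel$name_a[a], platform_b = unname(names_b),
         expected = .expected_overlap(panel))
  })
}

#' Generate per-IS dilution series for both platforms
#'
#' 7-point ladders spanning more than 2 orders of magnitude around each
#' standard's recommended concentration: linear responses on the untargeted
#' platform, linear-then-saturating on the targeted platform for the
#' saturating classes.
#'
#' @param config a [simulationConfig()] object.
#' @return list with `platform_a` and `platform_b` data.frames
#'   (`standard_id`, `lipid_class`, `nominal`, `recommended`, `response`).
#' @export
generateDilutionSeries <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .with_seed(config$seed, {
    panel <- .build_panel(config)
    is_panel <- .build_is_panel(config, panel)
    .build_dilution(config, is_panel)
  })
}

#' Null-study false discovery simulation
#'
#' Repeatedly simulates a study with no true effects (the configured panel,
#' biological variation and platform noise, but `effectFraction = 0`), runs
#' the per-lipid differential analysis, and records each repetition's false
#' discovery proportion at the stated FDR. On a fully null panel every
#' discovery is false, so the proportion is 1 whenever anything is called
#' significant and 0 otherwise; its mean estimates the realized FDR.
#'
#' @param config a [simulationConfig()] object (effects are ignored).
#' @param nRep number of repetitions.
#' @param fdr significance threshold.
#' @return Numeric vector of per-repetition false discovery proportions.
#' @export
nullFalseDiscoverySimulation <- function(config, nRep = 200, fdr = 0.05) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  nsp <- sum(cfg$panel)
  n_bio <- cfg$nYoung + cfg$nOld
  groups <- rep(c("young", "old"), c(cfg$nYoung, cfg$nOld))
  .with_seed(cfg$seed + 104729L, {
    base <- 10 * exp(stats::rnorm(nsp, 0, cfg$speciesLogSd))
    vapply(seq_len(nRep), function(r) {
      m <- base * exp(matrix(stats::rnorm(nsp * n_bio, 0, cfg$bioLogSd),
                             nsp, n_bio)) *
        matrix(.lnoise(nsp * n_bio, cfg$noiseCvA), nsp, n_bio)
      res <- differentialAnalysis(m, groups, fdr = fdr)
      n_sig <- sum(res$significant)
      if (n_sig > 0) 1 else 0
    }, numeric(1))
  })
}
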