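---
title: "Methods: cross-platform lipidomics harmonization and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform lipidomics harmonization and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidbridge` reproduces, as reusable and tested code, the computational
half of a paired-platform lipidomics comparison: one untargeted LC-MS
workflow producing relative feature abundances, one targeted MRM workflow
producing internal-standard-based concentrations, and the statistics that
connect them. This vignette is the package's own account of the models,
the assumptions behind them, and the design decisions taken where the
underlying procedures are ambiguous.

## Nomenclature model

A lipid shorthand name is parsed into a class token, an annotation level,
and fatty acyl chains. Four levels exist in the wild and in this package:

| level        | example               | meaning                                   |
|--------------|-----------------------|-------------------------------------------|
| `FULL_FA`    | `TAG(16:0/18:1/18:2)` | every chain resolved                      |
| `SUM`        | `PC(34:1)`, `SM(d38:1)` | total carbons:double bonds only         |
| `TAG_FA`     | `TAG52:3-FA16:0`      | sum composition + one anchored fatty acid |
| `SM_IMPLIED` | `SM(20:0)`            | N-acyl chain under an assumed d18:1 backbone |

Conversion to the targeted platform's reporting level follows two rules.
A `FULL_FA` TAG emits one `TAG_FA` annotation per **distinct** constituent
fatty acid — distinct, because the targeted platform cannot report the
same (sum, fatty acid) pair twice, so `TAG(16:0/16:0/16:0)` yields a
single annotation. A d-prefixed sphingolipid sum has 18 carbons and 1
double bond subtracted for the assumed d18:1 sphingoid backbone,
`SM(d38:1)` → `SM(20:0)`; sums with ≤ 18 carbons or no double bond cannot
host that backbone and raise a conversion error rather than a silent
wrap-around. We apply the same rule to d-prefixed ceramides: the targeted
platform reports CER by its N-acyl chain exactly as it does SM, and
without the extension no ceramide could ever match across platforms. All
other names pass through with canonical formatting.

Canonical text is the identity of an annotation: chains are stored sorted
ascending by (carbons, double bonds, ether link), so chain order in the
input never matters; ether-linked chains (`O-`/`P-`) keep their prefix and
can only match ether-linked chains; deuterium labels (`d5-` etc.) are
retained on internal-standard names but excluded from endogenous matching.
Set conversion deduplicates globally by canonical text, which is why a
converted list can be smaller than three times its TAG count.

Out of scope, deliberately: sn-position resolution, double-bond
position/geometry, oxidized or otherwise modified lipids, and the full
systematic nomenclature — the platforms being harmonized do not report
them.

## Targeted quantification

Each lipid is measured as 20 spectral scans. The vendor states only that
4 outlier scans are discarded and 16 averaged; the exact outlier rule is
unpublished. We discard the 4 scans with the largest absolute deviation
from the median of all 20, breaking ties by discarding the larger
intensity first, then by scan order. This is the simplest deterministic
reading; it is isolated in `trimmedScanMean()` so it can be swapped
without touching anything else.

Concentration follows the internal-standard ratio,

$$ c_\text{analyte} = \frac{\bar I_\text{analyte}}{\bar I_\text{IS}} \cdot c_\text{IS}, $$

in nmol/ml converted to nmol/g under the stated assumption that 1 ml of
plasma weighs 1 g. "Most structurally similar IS" is resolved as: same
lipid class, then smallest |Δ total carbons|, then smallest |Δ total
double bonds|, then lexicographic standard id — deterministic, and
recorded per lipid in an assignment audit. Negative scan intensities are
treated as corrupt input (error), not clamped to zero.

## Untargeted processing

The stage order is fixed: blank-feature removal → two-IS normalization →
presence filter → minimum imputation → adduct collapse. Each stage is
idempotent, and adducts are collapsed last because identification supplies
the lipid grouping. Numerical choices:

* *Blank removal* drops features whose mean blank intensity exceeds 0.5 ×
  their mean biological intensity (the source procedure names no
  threshold; 0.5 is configurable). The two spiked IS features are
  protected — they are present in solvent blanks by construction.
* *Normalization*: per sample, the factor is the mean over the two spiked
  IS of that IS's intensity divided by its cross-sample mean; every
  intensity is divided by the sample's factor. Referencing each IS to its
  cross-sample mean (rather than to a designated reference sample) makes
  the factors average to 1. This removes any per-sample multiplicative
  scale exactly, which is a property test in the suite.
* *Presence* means non-missing and strictly positive, and the filter is
  strictly greater than 50 % — detection in exactly half the samples
  fails, matching the stated wording.
* *Imputation* uses the per-lipid minimum observed value, not a global
  minimum, which would distort high-abundance classes; this is flagged as
  an assumption.
* *Adduct collapse* keeps the adduct with the highest mean biological
  intensity, exact ties going to the lexicographically first label.

## QC metrics

Precision is the coefficient of variation, $100\,s/\bar x$ with the
sample (n−1) standard deviation (the source does not specify the
denominator). Intra-day precision is the CV of five same-day replicate
injections; inter-day precision is the CV of the three daily medians, so
within-day scatter with stable medians contributes nothing.

Calibration curves are ordinary least squares of response on nominal
concentration over a 7-point dilution ladder spanning more than two
orders of magnitude, fitted on raw axes (the saturation phenomenology is
described on the response scale; a log-scale fit is a one-line swap).
r² is the squared Pearson correlation of the points used. Accuracy at the
recommended spike level uses the inverse-predicted concentration,
$(y_\text{rec} - \hat b)/\hat m$, in
$\%\,\text{accuracy} = |c_\text{calc} - c_\text{actual}|/c_\text{actual}\times 100$.
The estimator behind the published accuracy figures is not stated; inverse
prediction from the calibration fit is our choice, and the drop-highest
variant refits without the top ladder point — the documented remedy when
the top of the curve saturates.

## Cross-platform agreement

Per-lipid Pearson correlation is computed on untransformed values across
shared biological samples (correlation is invariant to positive affine
maps, so relative abundances compare directly against concentrations; a
log option exists but is off by default). TAG is excluded by default
because its two reporting levels do not identify the same molecules.
Zero-variance pairs have undefined r; they are flagged and excluded from
medians rather than coerced to 0, which would bias the median. Medians
over even counts are the mean of the central two throughout.

## Differential analysis

Per lipid, Welch's unequal-variance t-test compares old against young
(direction = sign of old mean − young mean, so "decreased" means decreased
with age); the implementation is the closed-form row-wise statistic with
Welch–Satterthwaite degrees of freedom, cross-checked in the tests against
`stats::t.test` to 1e-10. Multiplicity is controlled with
Benjamini–Hochberg step-up values used as q-values; the procedure behind
the published "q-value correction" is ambiguous, and BH was chosen for
determinism and monotonicity over Storey's π₀-smoothed estimator, which
would only shrink q-values. Significance is q ≤ 0.05, reading "an FDR of
0.05 or less" literally. Class totals are per-sample sums tested the same
way and reported as raw p-values — the published class-level values are
consistent with no multiplicity correction at that level. The
cross-platform consensus counts annotations significant on both platforms
with matching direction; direction disagreements are listed separately,
never silently merged.

## The synthetic study generator

No instrument data accompany this package (the original raw data are
available only on request), so validation rests on a generator whose
defaults *are* the study conditions, chosen once:

* panel of ~320 species dominated by TAG (100) and PC (60), 10–25 per
  remaining class, echoing their prevalence in plasma; species baselines
  lognormal around class-typical concentrations (TAG 20, PC 50, CE 100,
  … nmol/g) with log-sd 1;
* n = 10 + 10 biological samples; within-group biological variation
  lognormal with log-sd 0.2 (≈ 20 % CV);
* an age effect on half the panel, a 2-fold decrease applied to all TAG
  first and then a random remainder, with a small configurable fraction of
  increases — emulating a decline concentrated in TAG;
* platform injection noise of 5 % CV on both platforms, equal to the
  injected intra-day precision; per-sample extraction/injection scale
  factors (15 % CV) on the untargeted side, which the two spiked IS
  features track and normalization must remove;
* cross-platform correlation imposed on the biological log-deviations at
  ρ = 0.7 with the age effect shared between platforms — the two
  platforms see one biology through partially platform-specific
  distortions;
* hyperbolic detector saturation $y = x/(1 + x/h)$ on the targeted
  platform for TAG, DAG, CE and CER, with half-max $h$ at 4 × the class
  recommended concentration (`Inf` disables it) — the simplest monotone
  plateau. At this default the saturation is strong enough that the
  published drop-highest remedy measurably improves inverse-predicted
  accuracy, which is the acceptance check's subject;
* 20 scans per lipid with 2 % scan jitter, outlier scans at rate 0.05 and
  magnitude 5× (so the count of outliers rarely exceeds the 4 the
  trimming rule removes);
* 5 replicate injections × 3 days with a 5 % day effect; 7-point dilution
  ladders at 0.08–16 × the recommended level (200-fold span).

Everything is driven by one integer seed through a save/restore RNG
wrapper: identical seeds give bit-identical studies and, downstream,
byte-identical report bundles (fixed row ordering, 6-significant-digit
formatting).

The saturation acceptance check runs the dilution generator with
calibration noise set to zero: the check is structural (what the plateau
geometry does to the fit), and the noise-free limit isolates exactly that;
the study-level default keeps 5 % calibration noise for realism.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: chromatographic drift and retention-time
misalignment, isotope patterns and isobaric interference,
misidentification by spectral matching, correlated (batch) noise,
ion-suppression that differs by matrix, non-lognormal missingness
mechanisms (here missingness is random plus planted low-presence
features), and any real biology beyond a multiplicative two-group effect.
Recovery of the generating parameters demonstrates the pipeline's
correctness, not the platforms' field performance.

## Problem sizes

The test suite exercises a 57-species panel with n = 8 + 8 for speed; the
parameter-recovery acceptance check scales the same composition to 1,000
species with n = 10 + 10, 200 effect-free repetitions for the false
discovery check, and 500 lipids × 20 samples for correlation recovery.
These sizes were chosen as the smallest at which the medians and
proportions under test concentrate well inside their acceptance bands.

## Known limitations

* The outlier-scan rule and the structural-similarity metric are
  documented guesses at unpublished vendor logic, isolated behind single
  functions.
* Annotation matching is exact canonical-text equality; near-miss matching
  (e.g. a sum composition against a resolved species of the same sum) is
  intentionally not attempted.
* The published coverage counts can only be recomputed from the original
  supplementary identification lists, which are not redistributable here;
  the corresponding acceptance test states this and fails until those
  lists are supplied under `inst/extdata/`.
* Calibration fits are unweighted OLS; weighted or log-scale fits may
  behave differently at the extremes of the ladder.
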