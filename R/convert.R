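#' Convert a lipid name to the targeted reporting level
#'
#' Harmonizes one parsed name to the annotation level used by the targeted
#' platform so that coverage between an untargeted and a targeted run can be
#' compared species-by-species:
#' \itemize{
#'   \item a TAG with all three fatty acyls resolved yields one anchored
#'     annotation per \emph{distinct} constituent fatty acid, e.g.
#'     \code{TAG(16:0/18:1/18:2)} becomes \code{TAG52:3-FA16:0},
#'     \code{TAG52:3-FA18:1} and \code{TAG52:3-FA18:2}; duplicate chains
#'     collapse, so \code{TAG(16:0/16:0/16:0)} yields a single annotation;
#'   \item a d-prefixed sphingolipid sum composition is converted to its
#'     N-acyl chain under the assumed d18:1 backbone:
#'     \code{SM(d38:1)} becomes \code{SM(20:0)} (18 carbons and 1 double
#'     bond subtracted); the same rule is applied to \code{CER};
#'   \item every other name passes through at its given level with canonical
#'     formatting (chains sorted, class aliases canonicalized).
#' }
#'
#' @param name a [LipidName-class] object or a single shorthand string.
#' @return A [SpeciesAnnotations-class] set (1 to 3 annotations).
#' @examples
#' canonicalText(convertToTargetLevel("TAG(16:0/18:1/18:2)"))
#' canonicalText(convertToTargetLevel("SM(d38:1)"))
#' @export
convertToTargetLevel <- function(name) {
  if (is.character(name)) name <- parseLipidName(name)
  stopifnot(is(name, "LipidName"))
  cls <- name@lipidClass
  labeled <- name@deuterium > 0L

  if (cls == "TAG" && name@level == "FULL_FA") {
    ch <- name@chains
    key <- paste(ch$carbons, ch$double_bonds, ch$ether)
    ch <- ch[!duplicated(key), , drop = FALSE]
    return(.species_annotations(data.frame(
      lipid_class = cls, level = "TAG_FA",
      sum_carbons = name@sumCarbons, sum_double_bonds = name@sumDoubleBonds,
      anchor_carbons = ch$carbons, anchor_double_bonds = ch$double_bonds,
      ether = ch$ether, chain_text = "", sphingoid = FALSE,
      labeled = labeled, deuterium = name@deuterium,
      stringsAsFactors = FALSE)))
  }

  if (cls %in% c("SM", "CER") && name@level == "SUM" && name@sphingoidPrefix) {
    if (name@sumCarbons <= 18L || name@sumDoubleBonds < 1L)
      .conversion_error(sprintf(
        "cannot subtract the d18:1 backbone from '%s' (sum %d:%d)",
        name@raw, name@sumCarbons, name@sumDoubleBonds))
    return(.species_annotations(data.frame(
      lipid_class = cls, level = "SM_IMPLIED",
      sum_carbons = name@sumCarbons - 18L,
      sum_double_bonds = name@sumDoubleBonds - 1L,
      anchor_carbons = NA_integer_, anchor_double_bonds = NA_integer_,
      ether = "", chain_text = "", sphingoid = FALSE,
      labeled = labeled, deuterium = name@deuterium,
      stringsAsFactors = FALSE)))
  }

  if (cls %in% c("SM", "CER") && name@level == "FULL_FA") {
    # backbone resolved explicitly: report the N-acyl chain
    acyl <- name@chains[!name@chains$sphingoid, , drop = FALSE]
    return(.species_annotations(data.frame(
      lipid_class = cls, level = "SM_IMPLIED",
      sum_carbons = acyl$carbons[1L], sum_double_bonds = acyl$double_bonds[1L],
      anchor_carbons = NA_integer_, anchor_double_bonds = NA_integer_,
      ether = "", chain_text = "", sphingoid = FALSE,
      labeled = labeled, deuterium = name@deuterium,
      stringsAsFactors = FALSE)))
  }

  # pass-through at the given level with canonical formatting
  ch <- name@chains
  anchor_c <- NA_integer_; anchor_d <- NA_integer_; ether <- name@etherSum
  chain_text <- ""
  if (name@level == "TAG_FA") {
    anchor_c <- ch$carbons[1L]; anchor_d <- ch$double_bonds[1L]
    ether <- ch$ether[1L]
  } else if (name@level == "FULL_FA") {
    chain_text <- paste(.format_chain(ch$carbons, ch$double_bonds, ch$ether,
                                      ch$sphingoid), collapse = "/")
  }
  .species_annotations(data.frame(
    lipid_class = cls, level = name@level,
    sum_carbons = name@sumCarbons, sum_double_bonds = name@sumDoubleBonds,
    anchor_carbons = anchor_c, anchor_double_bonds = anchor_d,
    ether = ether, chain_text = chain_text,
    sphingoid = name@sphingoidPrefix, labeled = labeled,
    deuterium = name@deuterium, stringsAsFactors = FALSE))
}

#' Convert a list of names to a deduplicated annotation set
#'
#' Applies [convertToTargetLevel()] to every name and takes the union with
#' global deduplication by canonical text; the same annotation arising from
#' different precursors (e.g. two TAG species sharing a sum composition and a
#' fatty acid) is counted once.
#'
#' @param names character vector of shorthand names, or a list of
#'   [LipidName-class] objects.
#' @return A [SpeciesAnnotations-class] set; its `length()` is the unique
#'   annotation count.
#' @examples
#' length(convertNameSet(c("TAG(16:0/18:1/18:2)", "TAG(16:0/18:0/18:3)")))
#' @export
convertNameSet <- function(names) {
  if (length(names) == 0L) return(emptySpeciesAnnotations())
  sets <- lapply(names, function(nm) {
    tryCatch(convertToTargetLevel(nm), lipidbridgeError = function(e) {
      lab <- if (is.character(nm)) nm else nm@raw
      .conversion_error(sprintf("while converting '%s': %s", lab,
                                conditionMessage(e)))
    })
  })
  .combine_annotations(sets)
}

#' Match two annotation sets across platforms
#'
#' Computes the overlap of two sets of target-level annotations by canonical
#' text equality (which already compares chain multisets unordered and keeps
#' ether-linked chains distinct from ester-linked ones), plus per-class counts
#' and the Venn triple. Deuterated internal-standard annotations are excluded
#' from endogenous matching by default.
#'
#' @param set_a,set_b [SpeciesAnnotations-class] objects (empty sets allowed).
#' @param includeLabeled logical; keep deuterium-labeled annotations.
#' @return An object of class `"annotationOverlap"`: a list with elements
#'   `shared`, `a_only`, `b_only` (annotation sets), `venn` (named counts,
#'   conserved so that their sum equals the union size), `per_class`
#'   (data.frame of per-class counts) and `pct_of_a`/`pct_of_b` (shared as a
#'   percentage of each platform's coverage).
#' @export
matchAnnotations <- function(set_a, set_b, includeLabeled = FALSE) {
  stopifnot(is(set_a, "SpeciesAnnotations"), is(set_b, "SpeciesAnnotations"))
  if (!includeLabeled) {
    if (length(set_a)) set_a <- set_a[!set_a@df$labeled]
    if (length(set_b)) set_b <- set_b[!set_b@df$labeled]
  }
  ca <- canonicalText(set_a); cb <- canonicalText(set_b)
  shared <- set_a[ca %in% cb]
  a_only <- set_a[!ca %in% cb]
  b_only <- set_b[!cb %in% ca]

  classes <- sort(unique(c(lipidClass(set_a), lipidClass(set_b))))
  per_class <- data.frame(
    lipid_class = classes,
    n_a = vapply(classes, function(k) sum(lipidClass(set_a) == k), integer(1)),
    n_b = vapply(classes, function(k) sum(lipidClass(set_b) == k), integer(1)),
    n_shared = vapply(classes, function(k) sum(lipidClass(shared) == k),
                      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  out <- list(shared = shared, a_only = a_only, b_only = b_only,
              venn = c(a_only = length(a_only), shared = length(shared),
                       b_only = length(b_only)),
              n_union = length(a_only) + length(shared) + length(b_only),
              pct_of_a = if (length(set_a)) 100 * length(shared) / length(set_a)
                         else NA_real_,
              pct_of_b = if (length(set_b)) 100 * length(shared) / length(set_b)
                         else NA_real_,
              per_class = per_class)
  class(out) <- "annotationOverlap"
  out
}

#' @export
print.annotationOverlap <- function(x, ...) {
  cat(sprintf(
    "Cross-platform annotation overlap: %d shared, %d A-only, %d B-only (union %d)\n",
    x$venn[["shared"]], x$venn[["a_only"]], x$venn[["b_only"]], x$n_union))
  if (!is.na(x$pct_of_a))
    cat(sprintf("  shared = %.1f%% of platform A, %.1f%% of platform B\n",
                x$pct_of_a, x$pct_of_b))
  invisible(x)
}

#' Read a lipid name list
#'
#' Reads a plain-text or single-column CSV list of lipid names, one per line.
#' A header line is detected by attempting to parse it: if the first line is
#' not a valid shorthand name it is treated as a header and skipped.
#'
#' @param path file path.
#' @return Character vector of names.
#' @export
readNameList <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lines <- sub(",.*$", "", lines)  # tolerate trailing CSV columns
  if (length(lines) == 0L) return(character(0))
  first_ok <- tryCatch({ parseLipidName(lines[1L]); TRUE },
                       lipidParseError = function(e) FALSE)
  if (!first_ok) lines <- lines[-1L]
  lines
}

#' Write an overlap report
#'
#' @param overlap result of [matchAnnotations()].
#' @param path output CSV path; columns `annotation`, `in_platform_a`,
#'   `in_platform_b`, `lipid_class`, sorted by (class, annotation).
#' @return The path, invisibly.
#' @export
writeOverlapReport <- function(overlap, path) {
  stopifnot(inherits(overlap, "annotationOverlap"))
  part <- function(set, in_a, in_b) data.frame(
    annotation = canonicalText(set),
    in_platform_a = rep(in_a, length(set)),
    in_platform_b = rep(in_b, length(set)),
    lipid_class = lipidClass(set), stringsAsFactors = FALSE)
  rows <- rbind(part(overlap$shared, TRUE, TRUE),
                part(overlap$a_only, TRUE, FALSE),
                part(overlap$b_only, FALSE, TRUE))
  rows <- rows[order(rows$lipid_class, rows$annotation), , drop = FALSE]
  .write_report_csv(rows, path)
}
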