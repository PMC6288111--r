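#' @title Sum-composition lipid species annotations
#'
#' @description
#' `SpeciesAnnotations` is a vector-like container for lipid species
#' annotations at the reporting level used by targeted lipidomics platforms:
#' a lipid class plus total acyl carbons and double bonds, optionally with one
#' anchored fatty acid (the `TAG52:3-FA16:0` style) or, for names that already
#' resolve every chain, the full chain composition. Each annotation carries a
#' canonical text form; two annotations are the same species exactly when
#' their canonical texts are equal, which makes set operations (matching,
#' deduplication, Venn counts) unambiguous.
#'
#' @details
#' The canonical text conventions are:
#' \itemize{
#'   \item anchored fatty-acid level: \code{TAG52:3-FA16:0}
#'   \item sum composition: \code{PC(34:1)}, ether \code{PC(O-34:1)},
#'         sphingoid-prefixed \code{SM(d38:1)}
#'   \item backbone-implied N-acyl (sphingolipids): \code{SM(20:0)}
#'   \item full chain level: \code{PC(16:0/18:1)} with chains sorted
#'         ascending by (carbons, double bonds) so chain order never matters
#' }
#' Deuterated internal-standard names keep a \code{d5-} style prefix and are
#' flagged `labeled`; they are excluded from endogenous matching.
#'
#' @slot df data.frame with one row per annotation (class, level, sum
#'   composition, anchor, ether link, chain text, label flag, canonical text).
#'
#' @aliases SpeciesAnnotations-class
#' @export
setClass("SpeciesAnnotations", representation(df = "data.frame"))

.SA_COLS <- c("lipid_class", "level", "sum_carbons", "sum_double_bonds",
              "anchor_carbons", "anchor_double_bonds", "ether", "chain_text",
              "sphingoid", "labeled", "canonical_text")

.LIPID_CLASSES <- c("TAG", "DAG", "PC", "PE", "PI", "LPC", "LPE", "SM",
                    "CER", "CE", "FFA", "MISC")
.ANNOTATION_LEVELS <- c("FULL_FA", "SUM", "TAG_FA", "SM_IMPLIED")

setValidity("SpeciesAnnotations", function(object) {
  df <- object@df
  if (!all(.SA_COLS %in% names(df)))
    return(paste("missing columns:",
                 paste(setdiff(.SA_COLS, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$lipid_class %in% .LIPID_CLASSES))
    return("unknown lipid class")
  if (!all(df$level %in% .ANNOTATION_LEVELS))
    return("unknown annotation level")
  if (anyDuplicated(df$canonical_text))
    return("duplicated canonical_text; annotations must be unique")
  TRUE
})

.ether_prefix <- function(ether) {
  ifelse(is.na(ether) | ether == "", "", paste0(ether, "-"))
}

# Canonical text for one annotation row (vectorized over rows of a df).
.canonical_text <- function(df) {
  n <- nrow(df)
  out <- character(n)
  for (i in seq_len(n)) {
    core <- switch(df$level[i],
      TAG_FA = sprintf("%s%d:%d-FA%s%d:%d", df$lipid_class[i],
                       df$sum_carbons[i], df$sum_double_bonds[i],
                       .ether_prefix(df$ether[i]),
                       df$anchor_carbons[i], df$anchor_double_bonds[i]),
      SUM = sprintf("%s(%s%s%d:%d)", df$lipid_class[i],
                    .ether_prefix(df$ether[i]),
                    if (isTRUE(df$sphingoid[i])) "d" else "",
                    df$sum_carbons[i], df$sum_double_bonds[i]),
      SM_IMPLIED = sprintf("%s(%d:%d)", df$lipid_class[i],
                           df$sum_carbons[i], df$sum_double_bonds[i]),
      FULL_FA = sprintf("%s(%s)", df$lipid_class[i], df$chain_text[i]))
    if (isTRUE(df$labeled[i]) && !is.na(df$deuterium[i]) && df$deuterium[i] > 0)
      core <- sprintf("d%d-%s", df$deuterium[i], core)
    out[i] <- core
  }
  out
}

# Low-level constructor from a (possibly partial) data.frame; fills defaults,
# computes canonical text when absent, and deduplicates by canonical text.
.species_annotations <- function(df) {
  defaults <- list(anchor_carbons = NA_integer_, anchor_double_bonds = NA_integer_,
                   ether = "", chain_text = "", sphingoid = FALSE,
                   labeled = FALSE, deuterium = 0L)
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], length.out = nrow(df))
  }
  df$sum_carbons <- as.integer(df$sum_carbons)
  df$sum_double_bonds <- as.integer(df$sum_double_bonds)
  if (is.null(df$canonical_text)) df$canonical_text <- .canonical_text(df)
  df <- df[!duplicated(df$canonical_text), , drop = FALSE]
  rownames(df) <- NULL
  new("SpeciesAnnotations", df = df[, c(.SA_COLS, "deuterium"), drop = FALSE])
}

#' Construct a set of species annotations
#'
#' @param lipid_class character vector of class tokens (TAG, PC, ...).
#' @param sum_carbons,sum_double_bonds integer sum composition.
#' @param level annotation level; one of `"SUM"`, `"TAG_FA"`, `"SM_IMPLIED"`,
#'   `"FULL_FA"`.
#' @param anchor_carbons,anchor_double_bonds anchored fatty acid for
#'   `TAG_FA`-level annotations.
#' @param ether `""`, `"O"` or `"P"` ether link.
#' @param chain_text chain list (e.g. `"16:0/18:1"`) for `FULL_FA` rows.
#' @param labeled logical; `TRUE` marks deuterated internal-standard species.
#' @param deuterium integer deuterium count for labeled species.
#'
#' @return A [SpeciesAnnotations-class] object, deduplicated by canonical text.
#' @examples
#' SpeciesAnnotations("TAG", 52, 3, level = "TAG_FA",
#'                    anchor_carbons = 16, anchor_double_bonds = 0)
#' @export
SpeciesAnnotations <- function(lipid_class, sum_carbons, sum_double_bonds,
                               level = "SUM", anchor_carbons = NA_integer_,
                               anchor_double_bonds = NA_integer_, ether = "",
                               chain_text = "", labeled = FALSE,
                               deuterium = 0L) {
  df <- data.frame(lipid_class = lipid_class,
                   level = level,
                   sum_carbons = sum_carbons,
                   sum_double_bonds = sum_double_bonds,
                   anchor_carbons = as.integer(anchor_carbons),
                   anchor_double_bonds = as.integer(anchor_double_bonds),
                   ether = ether, chain_text = chain_text,
                   labeled = labeled, deuterium = as.integer(deuterium),
                   stringsAsFactors = FALSE)
  .species_annotations(df)
}

#' Empty annotation set
#' @return A zero-length [SpeciesAnnotations-class] object.
#' @export
emptySpeciesAnnotations <- function() {
  df <- data.frame(lipid_class = character(0), level = character(0),
                   sum_carbons = integer(0), sum_double_bonds = integer(0),
                   anchor_carbons = integer(0), anchor_double_bonds = integer(0),
                   ether = character(0), chain_text = character(0),
                   sphingoid = logical(0), labeled = logical(0),
                   deuterium = integer(0), canonical_text = character(0),
                   stringsAsFactors = FALSE)
  new("SpeciesAnnotations", df = df)
}

#' @describeIn SpeciesAnnotations Number of annotations in the set.
#' @param x a `SpeciesAnnotations` object.
#' @export
setMethod("length", "SpeciesAnnotations", function(x) nrow(x@df))

#' @rdname canonicalText
#' @export
setMethod("canonicalText", "SpeciesAnnotations", function(x) x@df$canonical_text)

#' @rdname lipidClass
#' @export
setMethod("lipidClass", "SpeciesAnnotations", function(x) x@df$lipid_class)

#' @rdname annotationLevel
#' @export
setMethod("annotationLevel", "SpeciesAnnotations", function(x) x@df$level)

#' @export
setMethod("as.data.frame", "SpeciesAnnotations",
          function(x, row.names = NULL, optional = FALSE, ...) x@df)

#' @export
setMethod("[", "SpeciesAnnotations", function(x, i, j, ..., drop = TRUE) {
  new("SpeciesAnnotations", df = x@df[i, , drop = FALSE])
})

#' @export
setMethod("show", "SpeciesAnnotations", function(object) {
  n <- length(object)
  cat(sprintf("SpeciesAnnotations with %d annotation%s\n", n,
              if (n == 1L) "" else "s"))
  if (n > 0L) {
    shown <- utils::head(canonicalText(object), 8L)
    cat(" ", paste(shown, collapse = ", "),
        if (n > 8L) sprintf(", ... (%d more)", n - 8L) else "", "\n", sep = "")
    tab <- table(lipidClass(object))
    cat("  classes:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

# Combine annotation sets with global deduplication by canonical text.
.combine_annotations <- function(sets) {
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (length(sets) == 0L) return(emptySpeciesAnnotations())
  df <- do.call(rbind, lapply(sets, function(s) s@df))
  .species_annotations(df)
}

#' @describeIn SpeciesAnnotations Union of annotation sets (deduplicated).
#' @param ... further `SpeciesAnnotations` objects.
#' @export
setMethod("c", "SpeciesAnnotations", function(x, ...) {
  .combine_annotations(c(list(x), list(...)))
})

#' @describeIn SpeciesAnnotations Deduplicate by canonical text (already the
#'   class invariant; provided for symmetry).
#' @param incomparables ignored.
#' @export
setMethod("unique", "SpeciesAnnotations", function(x, incomparables = FALSE, ...) x)
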