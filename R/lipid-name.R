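#' @title Parsed lipid shorthand name
#'
#' @description
#' `LipidName` is the structured parse of one lipid shorthand string as used
#' by untargeted LC-MS identification software and targeted platform reports.
#' The parser understands four syntactic levels:
#' \itemize{
#'   \item `FULL_FA` -- every fatty acyl listed, slash-separated:
#'     \code{TAG(16:0/18:1/18:2)}, \code{PC(O-16:0/18:1)},
#'     \code{SM(d18:1/20:0)}
#'   \item `SUM` -- total carbons:double bonds only: \code{PC(34:1)},
#'     \code{SM(d38:1)} (the leading \code{d} marks a sphingoid backbone,
#'     included in the totals)
#'   \item `TAG_FA` -- sum composition with one anchored fatty acid:
#'     \code{TAG52:3-FA16:0}
#'   \item `SM_IMPLIED` -- sphingolipid reported as its N-acyl chain under an
#'     assumed d18:1 backbone: \code{SM(20:0)}
#' }
#' A leading \code{d5-}/\code{d7-}/\code{d9-} token marks a deuterated
#' internal standard and is retained.
#'
#' @slot raw the original input string.
#' @slot lipidClass canonical class token (TAG, DAG, PC, PE, PI, LPC, LPE,
#'   SM, CER, CE, FFA, MISC).
#' @slot level one of FULL_FA, SUM, TAG_FA, SM_IMPLIED.
#' @slot chains data.frame of fatty acyls (carbons, double_bonds, ether,
#'   sphingoid), sorted canonically; empty at SUM level.
#' @slot sumCarbons,sumDoubleBonds integer sum composition.
#' @slot sphingoidPrefix logical; TRUE for d-prefixed sphingolipid sums.
#' @slot deuterium integer deuterium count (0 for endogenous lipids).
#'
#' @aliases LipidName-class
#' @export
setClass("LipidName", representation(
  raw = "character", lipidClass = "character", level = "character",
  chains = "data.frame", sumCarbons = "integer", sumDoubleBonds = "integer",
  sphingoidPrefix = "logical", etherSum = "character", deuterium = "integer"))

.CLASS_ALIASES <- c(TAG = "TAG", TG = "TAG", DAG = "DAG", DG = "DAG",
                    PC = "PC", PE = "PE", PI = "PI", LPC = "LPC", LPE = "LPE",
                    SM = "SM", CER = "CER", Cer = "CER", CE = "CE",
                    FFA = "FFA", FA = "FFA", MISC = "MISC")

# Expected chain count at FULL_FA level per class.
.CHAIN_COUNT <- c(TAG = 3L, DAG = 2L, PC = 2L, PE = 2L, PI = 2L,
                  LPC = 1L, LPE = 1L, SM = 2L, CER = 2L, CE = 1L, FFA = 1L)

setValidity("LipidName", function(object) {
  ch <- object@chains
  if (nrow(ch) > 0L) {
    if (any(ch$carbons < 1L)) return("chain carbons must be >= 1")
    if (any(ch$double_bonds < 0L)) return("chain double bonds must be >= 0")
    if (any(ch$double_bonds >= ch$carbons))
      return("chain double bonds must be fewer than carbons")
  }
  if (object@level == "FULL_FA") {
    if (sum(ch$carbons) != object@sumCarbons ||
        sum(ch$double_bonds) != object@sumDoubleBonds)
      return("sum composition inconsistent with chains")
  }
  TRUE
})

# Parse one chain token like "16:0", "O-16:0", "d18:1".
.parse_chain <- function(token, raw) {
  m <- regmatches(token, regexec("^(O-|P-)?(d)?([0-9]+):([0-9]+)$", token))[[1]]
  if (length(m) == 0L)
    .parse_error(sprintf("cannot parse chain token '%s' in '%s'", token, raw))
  carbons <- as.integer(m[4]); db <- as.integer(m[5])
  if (carbons < 1L)
    .parse_error(sprintf("chain '%s' in '%s': carbons must be >= 1", token, raw))
  if (db >= carbons)
    .parse_error(sprintf(
      "chain '%s' in '%s': double bonds must be fewer than carbons", token, raw))
  list(carbons = carbons, double_bonds = db,
       ether = if (m[2] == "") "" else substr(m[2], 1, 1),
       sphingoid = m[3] == "d")
}

.chain_df <- function(chains) {
  df <- data.frame(
    carbons = vapply(chains, `[[`, integer(1), "carbons"),
    double_bonds = vapply(chains, `[[`, integer(1), "double_bonds"),
    ether = vapply(chains, `[[`, character(1), "ether"),
    sphingoid = vapply(chains, `[[`, logical(1), "sphingoid"),
    stringsAsFactors = FALSE)
  # canonical order: sphingoid backbone first, then ascending (carbons,
  # double bonds, ether); chain order in the input never carries meaning here
  rest <- df[!df$sphingoid, , drop = FALSE]
  rest <- rest[order(rest$carbons, rest$double_bonds, rest$ether), , drop = FALSE]
  df <- rbind(df[df$sphingoid, , drop = FALSE], rest)
  rownames(df) <- NULL
  df
}

.empty_chain_df <- function() {
  data.frame(carbons = integer(0), double_bonds = integer(0),
             ether = character(0), sphingoid = logical(0),
             stringsAsFactors = FALSE)
}

.lookup_class <- function(token, raw) {
  if (!token %in% names(.CLASS_ALIASES))
    .parse_error(sprintf("unknown lipid class token '%s' in '%s'", token, raw))
  unname(.CLASS_ALIASES[token])
}

#' Parse a lipid shorthand name
#'
#' Turns a single shorthand string into a [LipidName-class] object, inferring
#' the annotation level from the syntax: slash-separated chains give
#' `FULL_FA`; a single carbons:double-bonds pair in parentheses gives `SUM`
#' (or `SM_IMPLIED` for non-d-prefixed sphingolipids); the
#' \code{TAG52:3-FA16:0} form gives `TAG_FA`. `TG`/`DG`/`Cer`/`FA` class
#' aliases are accepted and canonicalized to `TAG`/`DAG`/`CER`/`FFA`.
#'
#' @param text a single non-empty shorthand string.
#' @return A [LipidName-class] object.
#' @examples
#' parseLipidName("TAG(16:0/18:1/18:2)")
#' parseLipidName("SM(d38:1)")
#' parseLipidName("TAG52:3-FA16:0")
#' @seealso [convertToTargetLevel()], [formatLipidName()]
#' @export
parseLipidName <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    .parse_error("lipid name must be a single non-empty string")
  raw <- text
  s <- trimws(text)

  deuterium <- 0L
  m <- regmatches(s, regexec("^d([0-9]+)-(.+)$", s))[[1]]
  if (length(m) > 0L) {
    deuterium <- as.integer(m[2])
    s <- m[3]
  }

  # anchored fatty-acid form: TAG52:3-FA16:0
  m <- regmatches(s, regexec(
    "^([A-Za-z]+)[ ]?([0-9]+):([0-9]+)-FA(O-|P-)?([0-9]+):([0-9]+)$", s))[[1]]
  if (length(m) > 0L) {
    cls <- .lookup_class(m[2], raw)
    sc <- as.integer(m[3]); sd <- as.integer(m[4])
    anchor <- .parse_chain(paste0(m[5], m[6], ":", m[7]), raw)
    if (anchor$carbons > sc || anchor$double_bonds > sd)
      .parse_error(sprintf(
        "anchored fatty acid exceeds the sum composition in '%s'", raw))
    chains <- .chain_df(list(anchor))
    return(new("LipidName", raw = raw, lipidClass = cls, level = "TAG_FA",
               chains = chains, sumCarbons = sc, sumDoubleBonds = sd,
               sphingoidPrefix = FALSE, etherSum = "", deuterium = deuterium))
  }

  # parenthesized form: CLASS(...)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\(([^()]+)\\)$", s))[[1]]
  if (length(m) == 0L)
    .parse_error(sprintf("cannot parse lipid name '%s'", raw))
  cls <- .lookup_class(m[2], raw)
  tokens <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  chains <- lapply(tokens, .parse_chain, raw = raw)

  if (length(chains) == 1L) {
    ch <- chains[[1]]
    if (ch$sphingoid) {
      if (!cls %in% c("SM", "CER"))
        .parse_error(sprintf(
          "sphingoid 'd' prefix is only valid for SM/CER, not in '%s'", raw))
      return(new("LipidName", raw = raw, lipidClass = cls, level = "SUM",
                 chains = .empty_chain_df(), sumCarbons = ch$carbons,
                 sumDoubleBonds = ch$double_bonds, sphingoidPrefix = TRUE,
                 etherSum = "", deuterium = deuterium))
    }
    level <- if (cls %in% c("SM", "CER")) "SM_IMPLIED" else "SUM"
    return(new("LipidName", raw = raw, lipidClass = cls, level = level,
               chains = .empty_chain_df(), sumCarbons = ch$carbons,
               sumDoubleBonds = ch$double_bonds, sphingoidPrefix = FALSE,
               etherSum = ch$ether, deuterium = deuterium))
  }

  # multiple chains: FULL_FA, validated against the class chain count
  expected <- .CHAIN_COUNT[cls]
  if (is.na(expected))
    .parse_error(sprintf(
      "class '%s' does not support a full chain-level name ('%s')", cls, raw))
  if (length(chains) != expected)
    .parse_error(sprintf(
      "'%s': class %s requires %d chains at the full fatty-acyl level, got %d",
      raw, cls, expected, length(chains)))
  sph <- vapply(chains, `[[`, logical(1), "sphingoid")
  if (any(sph)) {
    if (!cls %in% c("SM", "CER") || sum(sph) != 1L || !sph[1L])
      .parse_error(sprintf(
        "misplaced sphingoid backbone chain in '%s'", raw))
  }
  if (cls %in% c("SM", "CER") && !any(sph))
    .parse_error(sprintf(
      "'%s': chain-level %s names need a d-prefixed backbone chain", raw, cls))
  chdf <- .chain_df(chains)
  new("LipidName", raw = raw, lipidClass = cls, level = "FULL_FA",
      chains = chdf, sumCarbons = sum(chdf$carbons),
      sumDoubleBonds = sum(chdf$double_bonds),
      sphingoidPrefix = any(sph), etherSum = "", deuterium = deuterium)
}

#' Parse a vector of lipid names
#'
#' @param texts character vector of shorthand names.
#' @return A list of [LipidName-class] objects, named by the input strings.
#'   Parse errors propagate and name the offending input.
#' @export
parseLipidNames <- function(texts) {
  out <- lapply(texts, parseLipidName)
  names(out) <- texts
  out
}

.format_chain <- function(carbons, double_bonds, ether, sphingoid) {
  sprintf("%s%s%d:%d", .ether_prefix(ether), ifelse(sphingoid, "d", ""),
          carbons, double_bonds)
}

#' Format a lipid name canonically
#'
#' Renders a [LipidName-class] in its canonical shorthand form (chains in
#' canonical order, canonical class tokens, deuterium prefix retained).
#' Formatting then re-parsing is the identity on the parsed structure.
#'
#' @param name a [LipidName-class] object.
#' @return A single character string.
#' @export
formatLipidName <- function(name) {
  stopifnot(is(name, "LipidName"))
  ch <- name@chains
  core <- switch(name@level,
    FULL_FA = sprintf("%s(%s)", name@lipidClass,
                      paste(.format_chain(ch$carbons, ch$double_bonds,
                                          ch$ether, ch$sphingoid),
                            collapse = "/")),
    SUM = sprintf("%s(%s%s%d:%d)", name@lipidClass,
                  .ether_prefix(name@etherSum),
                  if (name@sphingoidPrefix) "d" else "",
                  name@sumCarbons, name@sumDoubleBonds),
    SM_IMPLIED = sprintf("%s(%d:%d)", name@lipidClass, name@sumCarbons,
                         name@sumDoubleBonds),
    TAG_FA = sprintf("%s%d:%d-FA%s%d:%d", name@lipidClass, name@sumCarbons,
                     name@sumDoubleBonds, .ether_prefix(ch$ether[1L]),
                     ch$carbons[1L], ch$double_bonds[1L]))
  if (name@deuterium > 0L) core <- sprintf("d%d-%s", name@deuterium, core)
  core
}

#' @rdname lipidClass
#' @export
setMethod("lipidClass", "LipidName", function(x) x@lipidClass)

#' @rdname annotationLevel
#' @export
setMethod("annotationLevel", "LipidName", function(x) x@level)

#' Fatty acyl chains of a parsed name
#' @param name a [LipidName-class] object.
#' @return data.frame with columns carbons, double_bonds, ether, sphingoid.
#' @export
chains <- function(name) {
  stopifnot(is(name, "LipidName"))
  name@chains
}

#' Sum composition of a parsed name
#' @param name a [LipidName-class] object.
#' @return Named integer vector `c(carbons = , double_bonds = )`.
#' @export
sumComposition <- function(name) {
  stopifnot(is(name, "LipidName"))
  c(carbons = name@sumCarbons, double_bonds = name@sumDoubleBonds)
}

#' Compare two parsed lipid names structurally
#'
#' Equality ignores the raw input spelling (aliases, chain order) and compares
#' class, level, sum composition, chain multiset, sphingoid flag and
#' deuterium label.
#'
#' @param a,b [LipidName-class] objects.
#' @return `TRUE` or `FALSE`.
#' @export
sameLipid <- function(a, b) {
  stopifnot(is(a, "LipidName"), is(b, "LipidName"))
  identical(a@lipidClass, b@lipidClass) &&
    identical(a@level, b@level) &&
    identical(a@sumCarbons, b@sumCarbons) &&
    identical(a@sumDoubleBonds, b@sumDoubleBonds) &&
    identical(a@sphingoidPrefix, b@sphingoidPrefix) &&
    identical(a@deuterium, b@deuterium) &&
    identical(a@chains, b@chains)
}

#' @export
setMethod("show", "LipidName", function(object) {
  cat(sprintf("LipidName: %s [class %s, level %s, sum %d:%d%s%s]\n",
              formatLipidName(object), object@lipidClass, object@level,
              object@sumCarbons, object@sumDoubleBonds,
              if (object@sphingoidPrefix) ", sphingoid backbone" else "",
              if (object@deuterium > 0L)
                sprintf(", d%d-labeled", object@deuterium) else ""))
})
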