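# S4 generics, collated before any method definitions.

#' Canonical text of annotations or names
#'
#' @param x a [SpeciesAnnotations-class] object.
#' @return Character vector of canonical annotation strings.
#' @export
setGeneric("canonicalText", function(x) standardGeneric("canonicalText"))

#' Lipid class accessor
#' @param x an object carrying lipid class information
#'   ([LipidName-class] or [SpeciesAnnotations-class]).
#' @return Character vector of class tokens.
#' @export
setGeneric("lipidClass", function(x) standardGeneric("lipidClass"))

#' Annotation level accessor
#' @param x an object with an annotation level.
#' @return Character vector of levels (FULL_FA, SUM, TAG_FA, SM_IMPLIED).
#' @export
setGeneric("annotationLevel", function(x) standardGeneric("annotationLevel"))

#' Abundance matrix accessor
#' @param x a [LipidomicsExperiment-class].
#' @return Numeric matrix of abundances (lipids by samples).
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))
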