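#' @include AllClasses.R
NULL

#' Accessors for estimate-like objects
#'
#' `estimate()`, `stdError()`, `pValue()` and `confInt()` extract the point
#' estimate, standard error, p-value and 95% confidence bounds from
#' [MREstimate-class] and [EffectEstimate-class] objects; `oddsRatio()`
#' exponentiates a log-scale estimate and its bounds.
#'
#' @param object an estimate object.
#' @return numeric scalar (or length-2 vector for `confInt`).
#' @aliases estimate stdError pValue confInt oddsRatio
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' @rdname estimate
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))

#' @rdname estimate
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname estimate
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' @rdname estimate
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' Accessors for harmonized sets and instrument sets
#'
#' `variants()` returns the per-variant table, `droppedVariants()` the
#' reason-coded table of removed variants, `exposureNames()` the exposure
#' trait names and `nVariants()` the number of retained variants.
#'
#' @param object a [HarmonizedSet-class], [InstrumentSet-class] or
#'   [GwasSumstats-class] object (as applicable).
#' @return a `data.frame`, character vector or integer.
#' @aliases variants droppedVariants exposureNames nVariants
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))

#' @rdname variants
#' @export
setGeneric("droppedVariants", function(object) standardGeneric("droppedVariants"))

#' @rdname variants
#' @export
setGeneric("exposureNames", function(object) standardGeneric("exposureNames"))

#' @rdname variants
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))
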