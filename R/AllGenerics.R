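#' @rdname swapKeys
#' @export
setGeneric("swapKeys", function(x, a, b) standardGeneric("swapKeys"))

#' @rdname rotateSequence
#' @export
setGeneric("rotateSequence", function(x, offset) standardGeneric("rotateSequence"))

#' @rdname ordinalOverlap
#' @export
setGeneric("ordinalOverlap", function(x, y) standardGeneric("ordinalOverlap"))

#' @rdname keys
#' @export
setGeneric("keys", function(x) standardGeneric("keys"))

#' @rdname events
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname centerConditions
#' @export
setGeneric("centerConditions", function(x) standardGeneric("centerConditions"))

#' @rdname edgeEffectContrast
#' @export
setGeneric("edgeEffectContrast", function(x) standardGeneric("edgeEffectContrast"))

#' Number of cue events
#' @param x an \linkS4class{EventTimeline}.
#' @return integer count of cue rows.
#' @export
setGeneric("nCues", function(x) standardGeneric("nCues"))

#' t-value array accessor
#' @param x a \linkS4class{TPatternSet}.
#' @return the voxels x conditions x runs array.
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' Fisher-z similarity accessor
#' @param x a \linkS4class{SimilarityProfile}.
#' @return numeric length-8 vector of Fisher-z similarities.
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
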