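#' @export
setGeneric("normalizeProfiles", function(x, ...)
    standardGeneric("normalizeProfiles"))

#' @export
setGeneric("classSummary", function(x, ...)
    standardGeneric("classSummary"))

#' @export
setGeneric("nutritionalIndices", function(x, ...)
    standardGeneric("nutritionalIndices"))

#' @export
setGeneric("indexTable", function(x, ...)
    standardGeneric("indexTable"))

#' @export
setGeneric("glogTransform", function(x, lambda = NULL, ...)
    standardGeneric("glogTransform"))

#' @export
setGeneric("buildCurve", function(x, ...)
    standardGeneric("buildCurve"))

#' @export
setGeneric("estimateICx", function(x, level, ...)
    standardGeneric("estimateICx"))

#' @export
setGeneric("faCatalog", function(x) standardGeneric("faCatalog"))

#' @export
setGeneric("faSpecies", function(x) standardGeneric("faSpecies"))

#' @export
setGeneric("faReplicate", function(x) standardGeneric("faReplicate"))

#' @export
setGeneric("plateWells", function(x) standardGeneric("plateWells"))

#' @export
setGeneric("plateAssay", function(x) standardGeneric("plateAssay"))

#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @export
setGeneric("icValue", function(x) standardGeneric("icValue"))

#' @export
setGeneric("troloxEq", function(x) standardGeneric("troloxEq"))

#' @export
setGeneric("significanceLetters", function(x, ...)
    standardGeneric("significanceLetters"))
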