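#' @import methods
NULL

#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @export
setGeneric("mapName", function(x) standardGeneric("mapName"))

#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @export
setGeneric("bandwidthMatrix", function(x) standardGeneric("bandwidthMatrix"))
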