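#' @rdname foodGroups
#' @export
setGeneric("foodGroups", function(x) standardGeneric("foodGroups"))

#' @rdname foodGroups
#' @export
setGeneric("foodFractions", function(x) standardGeneric("foodFractions"))

#' @rdname foodGroups
#' @export
setGeneric("dietaryProxies", function(x) standardGeneric("dietaryProxies"))

#' @rdname foodGroups
#' @export
setGeneric("bulkFractions", function(x) standardGeneric("bulkFractions"))

#' @rdname foodGroups
#' @export
setGeneric("scenarioConstraints", function(x) standardGeneric("scenarioConstraints"))

#' @rdname foodGroups
#' @export
setGeneric("scenarioConstraints<-",
  function(x, value) standardGeneric("scenarioConstraints<-"))

#' @rdname logDensity
#' @export
setGeneric("logDensity", function(object, x, ...) standardGeneric("logDensity"))

#' @rdname logDensity
#' @export
setGeneric("sampleFrom", function(object, n, ...) standardGeneric("sampleFrom"))

#' @rdname nChains
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' @rdname nChains
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname nChains
#' @export
setGeneric("pooledDraws", function(x, params = NULL) standardGeneric("pooledDraws"))
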