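#' @rdname LatticeNetwork-class
#' @param object,x a \linkS4class{LatticeNetwork}
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname LatticeNetwork-class
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname LatticeNetwork-class
#' @export
setGeneric("meanDegree", function(object) standardGeneric("meanDegree"))

#' @rdname LatticeNetwork-class
#' @export
setGeneric("outDegree", function(object) standardGeneric("outDegree"))

#' @rdname SpikeExperiment
#' @export
setGeneric("spikeCounts", function(object) standardGeneric("spikeCounts"))

#' @rdname SpikeExperiment
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))

#' @rdname SpikeExperiment
#' @export
setGeneric("targetIds", function(object) standardGeneric("targetIds"))

#' @rdname TrialCounts-class
#' @param object a \linkS4class{TrialCounts}
#' @export
setGeneric("respCounts", function(object) standardGeneric("respCounts"))

#' @rdname TrialCounts-class
#' @export
setGeneric("baseCounts", function(object) standardGeneric("baseCounts"))

#' @rdname TrialCounts-class
#' @export
setGeneric("basePrimeCounts",
           function(object) standardGeneric("basePrimeCounts"))

#' @rdname TrialCounts-class
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))

#' @rdname TrialCounts-class
#' @export
setGeneric("unitInfo", function(object) standardGeneric("unitInfo"))
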