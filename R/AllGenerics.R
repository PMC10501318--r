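#' @rdname EpisodeSchedule-class
#' @param x,object an object.
#' @export
setGeneric("nEpisodes", function(x) standardGeneric("nEpisodes"))

#' @rdname EpisodeSchedule-class
#' @export
setGeneric("episodes", function(x) standardGeneric("episodes"))

#' @rdname EpisodeSchedule-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname MovieStack-class
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' @rdname MovieStack-class
#' @export
setGeneric("episodeBoundaries", function(x) standardGeneric("episodeBoundaries"))

#' @rdname RoiSet-class
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname RoiSet-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname RoiSet-class
#' @export
setGeneric("overlapPairs", function(x) standardGeneric("overlapPairs"))

#' @rdname TraceMatrix-class
#' @export
setGeneric("traceStage", function(x) standardGeneric("traceStage"))

#' @rdname TraceMatrix-class
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname GroundTruthCells-class
#' @export
setGeneric("cellInfo", function(x) standardGeneric("cellInfo"))

#' @rdname GroundTruthCells-class
#' @export
setGeneric("footprints", function(x) standardGeneric("footprints"))

#' @rdname ResponderTable-class
#' @export
setGeneric("responderCalls", function(x) standardGeneric("responderCalls"))

#' @rdname ResponderTable-class
#' @export
setGeneric("responderThreshold", function(x) standardGeneric("responderThreshold"))

#' @rdname ProportionSummary-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname ProportionSummary-class
#' @export
setGeneric("categoryPercentages", function(x) standardGeneric("categoryPercentages"))

#' @rdname SpatialActivityMap-class
#' @export
setGeneric("sdImage", function(x) standardGeneric("sdImage"))
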