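#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.STIMULUS_NAMES <- c("PUFF", "SKIN_BRUSH", "PINCH",
                     "COLON_BRUSH_INSERT", "COLON_BRUSH_EXTRACT",
                     "BALLOON_INSERT", "BALLOON_INFLATE")
.STIMULUS_SITES <- c(PUFF = "EXTERNAL", SKIN_BRUSH = "EXTERNAL",
                     PINCH = "EXTERNAL",
                     COLON_BRUSH_INSERT = "INTERNAL",
                     COLON_BRUSH_EXTRACT = "INTERNAL",
                     BALLOON_INSERT = "INTERNAL",
                     BALLOON_INFLATE = "INTERNAL")

.CELL_CLASSES <- c("INTERNAL_ONLY", "EXTERNAL_GENTLE", "EXTERNAL_NOXIOUS_ONLY",
                   "BOTH", "SILENT", "SPONTANEOUS", "PERSISTENT")

.CATEGORIES <- c("INTERNAL", "EXTERNAL_GENTLE", "EXTERNAL_NOXIOUS",
                 "EXCLUDED_BOTH", "EXCLUDED_SPONTANEOUS",
                 "EXCLUDED_PERSISTENT", "EXCLUDED_OVERLAP", "NONRESPONDER")
.INCLUDED_CATEGORIES <- c("INTERNAL", "EXTERNAL_GENTLE", "EXTERNAL_NOXIOUS")

.TRACE_STAGES <- c("RAW", "CORRECTED", "DFF")

#' Stimulation episode schedule
#'
#' Ordered list of stimulation episodes with per-episode frame counts,
#' baseline windows and stimulus identity, all sharing one frame rate.
#' Frames are 1-based; \code{onsetFrame} is the first post-baseline frame of
#' an episode and the response window runs from \code{onsetFrame} to
#' \code{nFrames} inclusive.
#'
#' @slot episodes data.frame with columns \code{stimulus}, \code{site},
#'   \code{nFrames}, \code{baselineFrames}, \code{onsetFrame},
#'   \code{offsetFrame}, \code{startFrame} (1-based first frame of the
#'   episode in the concatenated session).
#' @slot frameRateHz sampling rate in frames per second.
#' @exportClass EpisodeSchedule
setClass("EpisodeSchedule",
         representation(episodes = "data.frame", frameRateHz = "numeric"))

setValidity("EpisodeSchedule", function(object) {
    ep <- object@episodes
    need <- c("stimulus", "site", "nFrames", "baselineFrames",
              "onsetFrame", "offsetFrame", "startFrame")
    if (!all(need %in% names(ep)))
        return(paste("episodes must have columns:", paste(need, collapse = ", ")))
    if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
        return("frameRateHz must be a single positive number")
    if (nrow(ep) == 0L)
        return("schedule must contain at least one episode")
    if (!all(ep$site %in% c("EXTERNAL", "INTERNAL")))
        return("episode site must be EXTERNAL or INTERNAL")
    bad <- !(ep$baselineFrames < ep$onsetFrame &
             ep$onsetFrame <= ep$offsetFrame &
             ep$offsetFrame <= ep$nFrames)
    if (any(bad))
        return(paste("episode window invalid (need baselineFrames < onsetFrame",
                     "<= offsetFrame <= nFrames) for episode(s):",
                     paste(which(bad), collapse = ", ")))
    TRUE
})

#' Registered fluorescence movie stack
#'
#' A single H x W x T array of non-negative intensities holding the
#' concatenated episodes of one imaging session, together with the frame
#' rate and the 1-based start frame of each episode.
#'
#' @slot data numeric array, dimensions height x width x frames.
#' @slot frameRateHz frames per second.
#' @slot episodeBoundaries integer vector of 1-based episode start frames.
#' @exportClass MovieStack
setClass("MovieStack",
         representation(data = "array", frameRateHz = "numeric",
                        episodeBoundaries = "integer"))

setValidity("MovieStack", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L)
        return("data must be a 3-d array (height x width x frames)")
    if (any(object@data < 0))
        return("intensities must be non-negative")
    if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
        return("frameRateHz must be a single positive number")
    b <- object@episodeBoundaries
    if (length(b) == 0L || b[1L] != 1L || is.unsorted(b, strictly = TRUE) ||
        any(b > d[3L]))
        return("episodeBoundaries must be strictly increasing, start at 1 and not exceed the frame count")
    TRUE
})

#' Cell ROI label image with annulus geometry
#'
#' Integer label image (0 = background, k > 0 = cell k) plus the annulus
#' ("donut") geometry used for background correction and a record of ROI
#' pairs whose underlying footprints overlap. Overlaps cannot be represented
#' in a flat label image, so they are carried as construction metadata.
#'
#' @slot labels integer matrix, same height/width as the movie frames.
#' @slot annulusGapPx gap between footprint edge and inner annulus edge (px).
#' @slot annulusWidthPx radial width of the annulus (px).
#' @slot overlapPairs two-column integer matrix of overlapping label pairs
#'   (zero rows when no overlap was recorded).
#' @exportClass RoiSet
setClass("RoiSet",
         representation(labels = "matrix", annulusGapPx = "numeric",
                        annulusWidthPx = "numeric", overlapPairs = "matrix"))

setValidity("RoiSet", function(object) {
    lab <- object@labels
    if (any(lab < 0) || any(lab != round(lab)))
        return("labels must be non-negative integers")
    if (object@annulusGapPx < 0 || object@annulusWidthPx < 1)
        return("annulusGapPx must be >= 0 and annulusWidthPx >= 1")
    op <- object@overlapPairs
    if (ncol(op) != 2L)
        return("overlapPairs must have two columns")
    TRUE
})

#' Fluorescence trace matrix
#'
#' Cells x frames trace container built on
#' \linkS4class{SummarizedExperiment}: one assay \code{"traces"}, row
#' metadata carrying cell ids, column metadata carrying frame/episode
#' indices, and a processing-stage tag (\code{RAW} mean-footprint
#' fluorescence, \code{CORRECTED} after annulus subtraction, or \code{DFF}
#' percent dF/F).
#'
#' @slot stage one of \code{"RAW"}, \code{"CORRECTED"}, \code{"DFF"}.
#' @exportClass TraceMatrix
setClass("TraceMatrix",
         contains = "SummarizedExperiment",
         representation(stage = "character"))

setValidity("TraceMatrix", function(object) {
    if (length(object@stage) != 1L || !object@stage %in% .TRACE_STAGES)
        return(paste("stage must be one of:", paste(.TRACE_STAGES, collapse = ", ")))
    if (!"traces" %in% SummarizedExperiment::assayNames(object))
        return("assay 'traces' is required")
    if (is.null(metadata(object)$frameRateHz))
        return("metadata frameRateHz is required")
    TRUE
})

#' Ground-truthed synthetic cell population
#'
#' Cell footprints with planted response classes, transient amplitudes and
#' baseline levels, used by the movie renderer and as classification ground
#' truth in tests.
#'
#' @slot info data.frame with one row per cell: \code{cellId}, \code{class},
#'   \code{amplitudePct}, \code{baselineLevel}, \code{centerRow},
#'   \code{centerCol}, \code{radius}.
#' @slot footprints list of integer vectors of linear (column-major) pixel
#'   indices into the image.
#' @slot imageShape integer height/width of the field.
#' @slot overlapPairs two-column integer matrix of planted overlapping pairs.
#' @exportClass GroundTruthCells
setClass("GroundTruthCells",
         representation(info = "data.frame", footprints = "list",
                        imageShape = "integer", overlapPairs = "matrix"))

setValidity("GroundTruthCells", function(object) {
    info <- object@info
    if (nrow(info) != length(object@footprints))
        return("one footprint per info row required")
    if (nrow(info) > 0) {
        if (!all(info$class %in% .CELL_CLASSES))
            return("unknown planted class")
        resp <- !info$class %in% "SILENT"
        if (any(info$amplitudePct[resp] <= 0))
            return("transient amplitude must be > 0 for responding classes")
    }
    if (length(object@imageShape) != 2L)
        return("imageShape must be length 2")
    TRUE
})

#' Per-episode responder calls
#'
#' Long-format table of peak percent dF/F per cell and episode with the
#' strict threshold comparison (\code{peakDff > thresholdPct}).
#'
#' @slot calls data.frame with columns \code{cellId}, \code{episode},
#'   \code{stimulus}, \code{site}, \code{peakDff}, \code{isResponder}.
#' @slot thresholdPct activation threshold in percent dF/F.
#' @exportClass ResponderTable
setClass("ResponderTable",
         representation(calls = "data.frame", thresholdPct = "numeric"))

setValidity("ResponderTable", function(object) {
    need <- c("cellId", "episode", "stimulus", "site", "peakDff", "isResponder")
    if (!all(need %in% names(object@calls)))
        return(paste("calls must have columns:", paste(need, collapse = ", ")))
    if (length(object@thresholdPct) != 1L || object@thresholdPct <= 0)
        return("thresholdPct must be a single positive number")
    ok <- is.na(object@calls$peakDff) |
        (object@calls$isResponder == (object@calls$peakDff > object@thresholdPct))
    if (!all(ok, na.rm = TRUE))
        return("isResponder must equal (peakDff > thresholdPct)")
    TRUE
})

#' Pooled responder proportions
#'
#' Counts and percentages of the three included responder categories
#' (internal, external-gentle, external-noxious); pooled responders are
#' taken as 100 percent, excluded and non-responding cells enter neither
#' numerator nor denominator.
#'
#' @slot counts named integer vector over the three included categories.
#' @slot group free-text group label.
#' @exportClass ProportionSummary
setClass("ProportionSummary",
         representation(counts = "integer", group = "character"))

setValidity("ProportionSummary", function(object) {
    if (!identical(names(object@counts), .INCLUDED_CATEGORIES))
        return(paste("counts must be named:", paste(.INCLUDED_CATEGORIES, collapse = ", ")))
    if (any(object@counts < 0))
        return("counts must be non-negative")
    if (sum(object@counts) == 0L)
        return("at least one included responder is required")
    TRUE
})

#' Pixelwise standard-deviation activity map
#'
#' Per-pixel population standard deviation over all frames of all pooled
#' episodes of one stimulation site; bright pixels mark where fluorescence
#' changed most.
#'
#' @slot sdImage non-negative numeric matrix, movie frame shape.
#' @slot pooledSite \code{"EXTERNAL"} or \code{"INTERNAL"}.
#' @slot episodes integer indices of contributing episodes.
#' @exportClass SpatialActivityMap
setClass("SpatialActivityMap",
         representation(sdImage = "matrix", pooledSite = "character",
                        episodes = "integer"))

setValidity("SpatialActivityMap", function(object) {
    if (any(object@sdImage < 0))
        return("sdImage must be non-negative")
    if (!object@pooledSite %in% c("EXTERNAL", "INTERNAL"))
        return("pooledSite must be EXTERNAL or INTERNAL")
    if (length(object@episodes) < 1L)
        return("at least one contributing episode required")
    TRUE
})
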