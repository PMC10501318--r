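#' Stimulus catalogue for the seven-episode protocol
#'
#' The mechanical stimulation protocol applies, in order: an air puff,
#' gentle brushing and a pinch on the perineal skin (external site), then a
#' soft brush inserted into and extracted from the colon and a colonic
#' balloon inserted and inflated (internal site). \code{stimulusClasses()}
#' returns the catalogue with the site each stimulus maps to and a free-text
#' intensity label (puff durations in seconds, balloon pressures in mmHg).
#'
#' @param puffDurationsS air-puff durations pooled into the puff episode (s).
#' @param balloonPressuresMmHg balloon inflation pressures (mmHg).
#' @return data.frame with columns \code{name}, \code{site},
#'   \code{intensityLabel}.
#' @examples
#' stimulusClasses()
#' @export
stimulusClasses <- function(puffDurationsS = c(0.2, 1, 3, 5),
                            balloonPressuresMmHg = c(100, 150, 200)) {
    data.frame(
        name = .STIMULUS_NAMES,
        site = unname(.STIMULUS_SITES[.STIMULUS_NAMES]),
        intensityLabel = c(
            paste0("25 psi, ", paste(puffDurationsS, collapse = "/"), " s"),
            "manual gentle brush", "forceps pinch",
            "soft brush 6 cm", "soft brush extraction",
            "balloon placement 6 cm",
            paste(paste(balloonPressuresMmHg, collapse = "/"), "mmHg")),
        stringsAsFactors = FALSE)
}

#' Build the episode schedule
#'
#' Constructs an \linkS4class{EpisodeSchedule} from protocol constants.
#' Defaults reproduce the acquisition protocol: seven 40-s episodes sampled
#' at 5 Hz (200 frames each) with an 8-s (40-frame) baseline, stimulus onset
#' at the first post-baseline frame. Inter-episode pauses are represented by
#' episode boundaries, never by rendered dead frames.
#'
#' @param frameRateHz sampling rate, frames per second.
#' @param episodeS episode duration in seconds (scalar or one per episode).
#' @param baselineS baseline duration in seconds at the start of each episode.
#' @param stimuli data.frame as returned by [stimulusClasses()]; rows define
#'   the episodes in order.
#' @return an \linkS4class{EpisodeSchedule}.
#' @examples
#' sched <- generateSchedule()
#' nEpisodes(sched)
#' @export
generateSchedule <- function(frameRateHz = 5, episodeS = 40, baselineS = 8,
                             stimuli = stimulusClasses()) {
    if (length(frameRateHz) != 1L || !is.finite(frameRateHz) || frameRateHz <= 0)
        stop("invalid config: frameRateHz must be a positive number")
    if (any(!is.finite(episodeS)) || any(episodeS <= 0))
        stop("invalid config: episode duration must be positive")
    if (any(!is.finite(baselineS)) || any(baselineS <= 0))
        stop("invalid config: baseline duration must be positive")
    if (any(baselineS >= episodeS))
        stop("invalid config: baseline must be shorter than the episode")
    nEp <- nrow(stimuli)
    episodeS <- rep_len(episodeS, nEp)
    baselineS <- rep_len(baselineS, nEp)
    nFrames <- as.integer(round(episodeS * frameRateHz))
    baselineFrames <- as.integer(round(baselineS * frameRateHz))
    ep <- data.frame(
        stimulus = stimuli$name,
        site = stimuli$site,
        nFrames = nFrames,
        baselineFrames = baselineFrames,
        onsetFrame = baselineFrames + 1L,
        offsetFrame = nFrames,
        startFrame = as.integer(cumsum(c(1L, nFrames[-nEp]))),
        stringsAsFactors = FALSE)
    new("EpisodeSchedule", episodes = ep, frameRateHz = frameRateHz)
}

#' @rdname EpisodeSchedule-class
#' @export
setMethod("nEpisodes", "EpisodeSchedule", function(x) nrow(x@episodes))

#' @rdname EpisodeSchedule-class
#' @export
setMethod("episodes", "EpisodeSchedule", function(x) x@episodes)

#' @rdname EpisodeSchedule-class
#' @export
setMethod("frameRate", "EpisodeSchedule", function(x) x@frameRateHz)

#' Total session frame count of a schedule
#' @param schedule an \linkS4class{EpisodeSchedule}.
#' @return integer frame count summed over episodes.
#' @export
sessionFrames <- function(schedule) sum(episodes(schedule)$nFrames)

## Frame bookkeeping helpers (1-based, inclusive windows) ---------------------

.episodeFrameRange <- function(schedule, i) {
    ep <- episodes(schedule)
    start <- ep$startFrame[i]
    seq.int(start, start + ep$nFrames[i] - 1L)
}

.baselineFrameRange <- function(schedule, i) {
    ep <- episodes(schedule)
    start <- ep$startFrame[i]
    seq.int(start, start + ep$baselineFrames[i] - 1L)
}

.responseFrameRange <- function(schedule, i) {
    ep <- episodes(schedule)
    start <- ep$startFrame[i]
    seq.int(start + ep$onsetFrame[i] - 1L, start + ep$offsetFrame[i] - 1L)
}

setMethod("show", "EpisodeSchedule", function(object) {
    ep <- object@episodes
    cat("EpisodeSchedule:", nrow(ep), "episodes at", object@frameRateHz,
        "Hz (", sum(ep$nFrames), "frames total )\n")
    print(ep[, c("stimulus", "site", "nFrames", "baselineFrames",
                 "onsetFrame", "startFrame")])
    invisible(NULL)
})
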