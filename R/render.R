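## Which episodes a planted class responds to, derived from the schedule.
.responseEpisodes <- function(class, schedule) {
    ep <- episodes(schedule)
    internal <- which(ep$site == "INTERNAL")
    gentle <- which(ep$stimulus %in% c("PUFF", "SKIN_BRUSH"))
    pinch <- which(ep$stimulus == "PINCH")
    switch(class,
           INTERNAL_ONLY = internal,
           EXTERNAL_GENTLE = gentle,
           EXTERNAL_NOXIOUS_ONLY = pinch,
           BOTH = c(utils::head(gentle, 1L), utils::tail(internal, 1L)),
           SILENT = integer(0),
           SPONTANEOUS = integer(0),
           PERSISTENT = utils::head(c(internal, seq_len(nrow(ep))), 1L),
           stop("unknown planted class: ", class))
}

## Session-long response kernel in [0, 1]; peak is exactly 1 so that the
## planted amplitude is realized exactly at the transient peak.
.responseKernel <- function(class, schedule, tauFrames) {
    total <- sessionFrames(schedule)
    k <- numeric(total)
    ep <- episodes(schedule)
    for (e in .responseEpisodes(class, schedule)) {
        onset <- ep$startFrame[e] + ep$onsetFrame[e] - 1L
        epEnd <- ep$startFrame[e] + ep$nFrames[e] - 1L
        if (class == "PERSISTENT") {
            # stays elevated from first response through the final frame
            k[onset:total] <- 1
            break
        }
        decay <- exp(-(seq.int(0L, epEnd - onset)) / tauFrames)
        k[onset:epEnd] <- pmax(k[onset:epEnd], decay)
    }
    if (class == "SPONTANEOUS") {
        # transient confined to the first episode's baseline window
        bFrames <- ep$baselineFrames[1L]
        onset <- ep$startFrame[1L] + max(1L, bFrames %/% 4L) - 1L
        epEnd <- ep$startFrame[1L] + ep$nFrames[1L] - 1L
        decay <- exp(-(seq.int(0L, epEnd - onset)) / tauFrames)
        k[onset:epEnd] <- pmax(k[onset:epEnd], decay)
    }
    k
}

## Separable small-sigma Gaussian blur of an H x W weight image (halo option).
.gaussBlur <- function(img, sigma) {
    half <- max(1L, ceiling(3 * sigma))
    kern <- exp(-(seq.int(-half, half))^2 / (2 * sigma^2))
    kern <- kern / sum(kern)
    blur1 <- function(m) {   # along rows
        out <- m * kern[half + 1L]
        for (o in seq_len(half)) {
            n <- nrow(m)
            out[(o + 1L):n, ] <- out[(o + 1L):n, ] + kern[half + 1L - o] * m[1:(n - o), ]
            out[1:(n - o), ] <- out[1:(n - o), ] + kern[half + 1L + o] * m[(o + 1L):n, ]
        }
        out
    }
    t(blur1(t(blur1(img))))
}

#' Render a synthetic calcium-imaging movie
#'
#' Renders a registered movie stack from planted cells and an episode
#' schedule. Each responding cell carries a GCaMP6f-like transient — an
#' instantaneous rise at stimulus onset followed by exponential decay with
#' time constant \code{tauS} — whose noise-free peak percent change over the
#' cell's baseline equals the planted amplitude. Cells planted as
#' \code{SPONTANEOUS} fire during the first episode's baseline window;
#' \code{PERSISTENT} cells stay elevated from their first response to the
#' final frame. A spatially uniform background with sinusoidal drift is
#' added to every pixel, i.i.d. Gaussian sensor noise is added last, and
#' intensities are clipped at zero.
#'
#' The background is additive and spatially uniform by design, which makes
#' annulus subtraction exact on synthetic data; an optional halo
#' (\code{haloSigma > 0}) blurs each cell's spatial weight to emulate local
#' out-of-focus contamination instead.
#'
#' @param cells a \linkS4class{GroundTruthCells}.
#' @param schedule an \linkS4class{EpisodeSchedule}.
#' @param backgroundLevel mean background intensity.
#' @param backgroundDriftAmplitude amplitude of the sinusoidal background
#'   drift (same units).
#' @param driftPeriodS drift period in seconds.
#' @param noiseSd standard deviation of the Gaussian sensor noise (>= 0).
#' @param tauS transient decay time constant in seconds.
#' @param haloSigma Gaussian sigma (px) for optional halo contamination;
#'   0 disables it.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone (the
#'   render is then only reproducible if \code{noiseSd == 0}).
#' @return a \linkS4class{MovieStack}.
#' @examples
#' sched <- generateSchedule()
#' cells <- generateCells(c(INTERNAL_ONLY = 2), imageShape = c(48, 48), seed = 1)
#' mov <- renderMovie(cells, sched, noiseSd = 0, seed = 1)
#' dim(movieData(mov))
#' @export
renderMovie <- function(cells, schedule,
                        backgroundLevel = 100,
                        backgroundDriftAmplitude = 10,
                        driftPeriodS = 60,
                        noiseSd = 2,
                        tauS = 1,
                        haloSigma = 0,
                        seed = NULL) {
    stopifnot(is(cells, "GroundTruthCells"), is(schedule, "EpisodeSchedule"))
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    shape <- cells@imageShape
    H <- shape[1L]; W <- shape[2L]
    total <- sessionFrames(schedule)
    rate <- frameRate(schedule)
    tauFrames <- tauS * rate

    tSec <- (seq_len(total) - 1L) / rate
    bg <- backgroundLevel +
        backgroundDriftAmplitude * sin(2 * pi * tSec / driftPeriodS)
    m <- matrix(rep(bg, each = H * W), nrow = H * W, ncol = total)

    info <- cells@info
    for (i in seq_len(nrow(info))) {
        k <- .responseKernel(info$class[i], schedule, tauFrames)
        trace <- info$baselineLevel[i] * (1 + k * info$amplitudePct[i] / 100)
        if (haloSigma > 0) {
            w <- matrix(0, H, W)
            w[cells@footprints[[i]]] <- 1
            w <- .gaussBlur(w, haloSigma)
            idx <- which(w > 1e-8)
            m[idx, ] <- m[idx, ] + outer(w[idx], trace)
        } else {
            idx <- cells@footprints[[i]]
            m[idx, ] <- m[idx, ] + rep(trace, each = length(idx))
        }
    }
    if (noiseSd > 0)
        m <- m + stats::rnorm(length(m), mean = 0, sd = noiseSd)
    m[m < 0] <- 0
    new("MovieStack",
        data = array(m, dim = c(H, W, total)),
        frameRateHz = rate,
        episodeBoundaries = episodes(schedule)$startFrame)
}

#' @rdname MovieStack-class
#' @export
setMethod("movieData", "MovieStack", function(x) x@data)

#' @rdname MovieStack-class
#' @export
setMethod("episodeBoundaries", "MovieStack", function(x) x@episodeBoundaries)

#' @rdname MovieStack-class
#' @export
setMethod("frameRate", "MovieStack", function(x) x@frameRateHz)

#' @rdname MovieStack-class
#' @export
setMethod("dim", "MovieStack", function(x) dim(x@data))

setMethod("show", "MovieStack", function(object) {
    d <- dim(object@data)
    cat("MovieStack:", d[1L], "x", d[2L], "px,", d[3L], "frames at",
        object@frameRateHz, "Hz;", length(object@episodeBoundaries),
        "episodes\n")
    invisible(NULL)
})

#' Construct a MovieStack from an array
#'
#' @param data H x W x T non-negative numeric array.
#' @param frameRateHz frames per second.
#' @param episodeBoundaries 1-based episode start frames.
#' @return a \linkS4class{MovieStack}.
#' @export
movieStack <- function(data, frameRateHz, episodeBoundaries = 1L) {
    new("MovieStack", data = data, frameRateHz = frameRateHz,
        episodeBoundaries = as.integer(episodeBoundaries))
}
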