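#' Gastric emptying percentage
#'
#' Compares the radiant efficiency measured over the stomach with the rest
#' of the small and large intestines and expresses both shares as
#' percentages of the total gut signal. Emptying is the non-stomach share
#' (marker that has left the stomach); the complementary stomach-retention
#' percentage is co-reported so either orientation is recoverable.
#'
#' @param regionSignal data.frame with columns \code{stomachSignal} and
#'   \code{restOfGutSignal} (same units, both >= 0).
#' @return data.frame with \code{emptyingPct} and \code{retentionPct} per
#'   sample (rows preserved).
#' @examples
#' gastricEmptyingPct(data.frame(stomachSignal = 25, restOfGutSignal = 75))
#' @export
gastricEmptyingPct <- function(regionSignal) {
    s <- regionSignal$stomachSignal
    r <- regionSignal$restOfGutSignal
    if (any(s < 0) || any(r < 0))
        stop("signals must be non-negative")
    total <- s + r
    if (any(total <= 0))
        stop("zero total signal for sample(s): ",
             paste(which(total <= 0), collapse = ", "))
    data.frame(emptyingPct = 100 * r / total,
               retentionPct = 100 * s / total)
}

#' Whole-mount nerve density
#'
#' Nerve density over a field: NerveArea / TotalArea, the fraction of field
#' pixels covered by segmented nerve fibres (fields follow the 80 um x
#' 80 um region convention; masks are consumed pre-segmented).
#'
#' @param nerveMask logical (or 0/1) matrix marking nerve pixels.
#' @param fieldArea total field area in pixels; defaults to
#'   \code{length(nerveMask)}.
#' @return density in [0, 1].
#' @export
nerveDensity <- function(nerveMask, fieldArea = length(nerveMask)) {
    if (fieldArea <= 0) stop("empty field")
    nerve <- sum(nerveMask != 0)
    if (nerve > fieldArea)
        stop("nerve pixels exceed the field area")
    nerve / fieldArea
}

#' Intraganglionic varicose ending (IGVE) density
#'
#' Density of labeled (innervated) enteric ganglia per field:
#' LabeledGanglia / TotalArea, reported per pixel and per 1000 square
#' pixels.
#'
#' @param gangliaCount number of innervated ganglia counted in the field.
#' @param fieldArea field area in pixels (> 0).
#' @return data.frame with \code{perPx} and \code{per1000Px}.
#' @export
igveDensity <- function(gangliaCount, fieldArea) {
    if (fieldArea <= 0) stop("empty field")
    if (gangliaCount < 0) stop("ganglia count must be >= 0")
    data.frame(perPx = gangliaCount / fieldArea,
               per1000Px = 1000 * gangliaCount / fieldArea)
}

#' Stool water content percentage
#'
#' Water content of a stool sample from fresh (wet) and oven-dried weights:
#' \code{100 * (wet - dry) / wet}.
#'
#' @param stool data.frame with columns \code{wetWeightMg} and
#'   \code{dryWeightMg}.
#' @return numeric vector of water-content percentages.
#' @examples
#' waterContentPct(data.frame(wetWeightMg = 40, dryWeightMg = 10))
#' @export
waterContentPct <- function(stool) {
    wet <- stool$wetWeightMg
    dry <- stool$dryWeightMg
    if (any(wet <= 0)) stop("wet weight must be > 0")
    if (any(dry < 0)) stop("dry weight must be >= 0")
    if (any(dry > wet))
        stop("data error: dry weight exceeds wet weight for sample(s): ",
             paste(which(dry > wet), collapse = ", "))
    100 * (wet - dry) / wet
}

#' Otsu threshold helper for synthetic nerve images
#'
#' Binarises a grayscale image by Otsu's method (histogram-based
#' between-class variance maximisation). Intended for segmenting synthetic
#' nerve fields in examples and tests; real masks are consumed
#' pre-segmented.
#'
#' @param img numeric matrix.
#' @param nBins histogram bins.
#' @return logical matrix (\code{TRUE} = foreground).
#' @export
otsuMask <- function(img, nBins = 256) {
    rng <- range(img)
    if (diff(rng) == 0) return(img > rng[1L])   # flat image: nothing above
    breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
    h <- tabulate(findInterval(img, breaks, all.inside = TRUE), nBins)
    p <- h / sum(h)
    mids <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
    w0 <- cumsum(p)
    mu <- cumsum(p * mids)
    muT <- mu[nBins]
    between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
    between[!is.finite(between)] <- 0
    img > mids[which.max(between)]
}
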