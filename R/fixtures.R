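#' Generate ground-truthed fixtures for the gut quantification ratios
#'
#' Produces small synthetic tables and masks for the four quantification
#' ratios — gastric emptying (stomach vs. total radiant efficiency), stool
#' water content (wet/dry weights), whole-mount nerve density (binary mask
#' over a field) and intraganglionic varicose ending (IGVE) density — with
#' the true ratio of every record computed at generation time and stored
#' alongside, so downstream arithmetic can be checked to machine precision.
#'
#' @param nSamples number of records per table.
#' @param fieldSize side length in pixels of the square nerve-density field
#'   (the 80 um x 80 um region convention at 1 px/um).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return list with elements \code{regionSignal} (data.frame: sample,
#'   stomachSignal, restOfGutSignal, truthEmptyingPct), \code{stool}
#'   (data.frame: sample, wetWeightMg, dryWeightMg, widthMm, lengthMm,
#'   truthWaterPct), \code{nerveMask} (logical matrix), \code{gangliaCount},
#'   \code{fieldArea}, and \code{groundTruth} (list of the planted ratios).
#' @examples
#' fx <- generateQuantFixtures(seed = 1)
#' fx$groundTruth$nerveDensity
#' @export
generateQuantFixtures <- function(nSamples = 6, fieldSize = 80, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)

    stomachShare <- stats::runif(nSamples, 0.15, 0.85)
    total <- stats::runif(nSamples, 5e8, 5e9)   # radiant-efficiency scale
    regionSignal <- data.frame(
        sample = seq_len(nSamples),
        stomachSignal = stomachShare * total,
        restOfGutSignal = (1 - stomachShare) * total,
        truthEmptyingPct = 100 * (1 - stomachShare))

    wet <- stats::runif(nSamples, 20, 60)        # mg, fresh mouse pellets
    waterFrac <- stats::runif(nSamples, 0.4, 0.8)
    stool <- data.frame(
        sample = seq_len(nSamples),
        wetWeightMg = wet,
        dryWeightMg = wet * (1 - waterFrac),
        widthMm = stats::runif(nSamples, 1.5, 4),
        lengthMm = stats::runif(nSamples, 3, 10),
        truthWaterPct = 100 * waterFrac)

    fieldArea <- fieldSize^2
    nNerve <- as.integer(round(stats::runif(1, 0.1, 0.6) * fieldArea))
    nerveMask <- matrix(FALSE, fieldSize, fieldSize)
    nerveMask[sample.int(fieldArea, nNerve)] <- TRUE

    gangliaCount <- sample.int(9L, 1L) - 1L      # 0..8 innervated ganglia

    list(regionSignal = regionSignal,
         stool = stool,
         nerveMask = nerveMask,
         gangliaCount = gangliaCount,
         fieldArea = fieldArea,
         groundTruth = list(
             emptyingPct = regionSignal$truthEmptyingPct,
             waterPct = stool$truthWaterPct,
             nerveDensity = nNerve / fieldArea,
             igveDensity = gangliaCount / fieldArea))
}
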