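#' Pipeline configuration
#'
#' One plain named list drives every stage; each protocol constant is a
#' default here, never hard-coded downstream. Round-trips losslessly
#' through YAML via [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param frameRateHz sampling rate (Hz).
#' @param episodeS,baselineS episode and baseline durations (s).
#' @param puffDurationsS pooled air-puff durations (s).
#' @param balloonPressuresMmHg balloon pressures (mmHg).
#' @param thresholdPct activation threshold, percent dF/F.
#' @param annulusGapPx,annulusWidthPx annulus geometry (px).
#' @param spontaneousConsecFrames,persistentFrac exclusion-rule parameters.
#' @param imageShape simulated field height/width (px).
#' @param footprintRadius simulated cell radius (px).
#' @param nPerClass named counts of planted cells per class.
#' @param amplitudePct planted transient amplitude (percent dF/F).
#' @param baselineLevel planted baseline fluorescence.
#' @param backgroundLevel,backgroundDriftAmplitude,driftPeriodS background
#'   model parameters.
#' @param noiseSd Gaussian sensor-noise SD.
#' @param tauS transient decay constant (s).
#' @param plantOverlap plant one overlapping ROI pair.
#' @param seed master seed for the simulated session.
#' @return named list of class \code{"drgPipelineConfig"}.
#' @export
pipelineConfig <- function(frameRateHz = 5, episodeS = 40, baselineS = 8,
                           puffDurationsS = c(0.2, 1, 3, 5),
                           balloonPressuresMmHg = c(100, 150, 200),
                           thresholdPct = 5,
                           annulusGapPx = 1, annulusWidthPx = 3,
                           spontaneousConsecFrames = 3, persistentFrac = 0.8,
                           imageShape = c(256L, 256L), footprintRadius = 4,
                           nPerClass = .defaultCellCounts(),
                           amplitudePct = 20, baselineLevel = 100,
                           backgroundLevel = 100,
                           backgroundDriftAmplitude = 10, driftPeriodS = 60,
                           noiseSd = 2, tauS = 1, plantOverlap = FALSE,
                           seed = 1L) {
    cfg <- list(frameRateHz = frameRateHz, episodeS = episodeS,
                baselineS = baselineS, puffDurationsS = puffDurationsS,
                balloonPressuresMmHg = balloonPressuresMmHg,
                thresholdPct = thresholdPct, annulusGapPx = annulusGapPx,
                annulusWidthPx = annulusWidthPx,
                spontaneousConsecFrames = spontaneousConsecFrames,
                persistentFrac = persistentFrac,
                imageShape = as.integer(imageShape),
                footprintRadius = footprintRadius,
                nPerClass = as.list(nPerClass),
                amplitudePct = amplitudePct, baselineLevel = baselineLevel,
                backgroundLevel = backgroundLevel,
                backgroundDriftAmplitude = backgroundDriftAmplitude,
                driftPeriodS = driftPeriodS, noiseSd = noiseSd, tauS = tauS,
                plantOverlap = plantOverlap, seed = as.integer(seed))
    class(cfg) <- "drgPipelineConfig"
    validatePipelineConfig(cfg)
    cfg
}

#' @rdname pipelineConfig
#' @param config a configuration list.
#' @export
validatePipelineConfig <- function(config) {
    with(config, {
        if (frameRateHz <= 0 || episodeS <= 0 || baselineS <= 0)
            stop("config validation error: durations and rates must be positive")
        if (baselineS >= episodeS)
            stop("config validation error: baseline must be shorter than episode")
        if (thresholdPct <= 0)
            stop("config validation error: thresholdPct must be > 0")
        if (noiseSd < 0)
            stop("config validation error: noiseSd must be >= 0")
        if (annulusGapPx < 0 || annulusWidthPx < 1)
            stop("config validation error: invalid annulus geometry")
    })
    invisible(config)
}

#' @rdname pipelineConfig
#' @param path .yaml path.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    cfg$imageShape <- as.integer(cfg$imageShape)
    cfg$seed <- as.integer(cfg$seed)
    class(cfg) <- "drgPipelineConfig"
    validatePipelineConfig(cfg)
    cfg
}

#' Validate pipeline inputs
#'
#' Checks movie/ROI shape agreement, schedule/frame-count agreement and
#' label contiguity, distinguishing warnings from fatal errors.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param rois a \linkS4class{RoiSet}.
#' @param schedule an \linkS4class{EpisodeSchedule}.
#' @return data.frame with columns \code{level} (\code{"error"} or
#'   \code{"warning"}) and \code{message}; zero rows when everything agrees.
#' @export
validateInputs <- function(movie, rois, schedule) {
    findings <- list()
    add <- function(level, msg)
        findings[[length(findings) + 1L]] <<- data.frame(level = level,
                                                         message = msg)
    d <- dim(movie@data)
    if (!identical(dim(rois@labels), d[1:2]))
        add("error", sprintf("label image %s does not match movie frames %s",
                             paste(dim(rois@labels), collapse = "x"),
                             paste(d[1:2], collapse = "x")))
    if (sessionFrames(schedule) != d[3L])
        add("error", sprintf("movie has %d frames but schedule expects %d",
                             d[3L], sessionFrames(schedule)))
    if (!identical(as.integer(episodes(schedule)$startFrame),
                   movie@episodeBoundaries))
        add("warning", "movie episode boundaries differ from the schedule")
    labs <- sort(unique(as.vector(rois@labels)))
    labs <- labs[labs > 0]
    if (!length(labs))
        add("error", "no ROIs: label image contains label 0 only")
    else if (!identical(labs, seq_len(max(labs))))
        add("warning", sprintf("label ids not contiguous: missing %s",
                               paste(setdiff(seq_len(max(labs)), labs),
                                     collapse = ", ")))
    if (length(findings)) do.call(rbind, findings) else
        data.frame(level = character(0), message = character(0))
}

#' Run the full simulated-session pipeline
#'
#' Chains every stage deterministically from one config: simulate (schedule,
#' cells, movie), extract, annulus-correct, percent dF/F, responder calls,
#' exclusions, classification, pooled proportions, SD activity maps and the
#' sorted heatmap layout, then writes the report bundle to \code{outDir}:
#' \code{classification.csv}, \code{responders.csv}, \code{proportions.csv},
#' \code{sd_external.tif}, \code{sd_internal.tif}, \code{heatmap_layout.csv},
#' \code{schedule.json}, \code{ground_truth.json}, \code{config.yaml} and a
#' \code{manifest.json} carrying the config hash, package/R versions, the
#' seed and per-file MD5 checksums. Given the same config (same seed) two
#' runs produce bit-identical bundles.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return invisible list with all in-memory stage results and
#'   \code{files}, the written paths.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
    validatePipelineConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- function(stage, fmt, ...)
        message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

    schedule <- generateSchedule(config$frameRateHz, config$episodeS,
                                 config$baselineS,
                                 stimulusClasses(config$puffDurationsS,
                                                 config$balloonPressuresMmHg))
    cells <- generateCells(unlist(config$nPerClass), config$imageShape,
                           config$footprintRadius, config$amplitudePct,
                           config$baselineLevel,
                           plantOverlap = isTRUE(config$plantOverlap),
                           seed = config$seed)
    log("simulate", "%d cells on a %s field, %d episodes",
        nrow(cellInfo(cells)), paste(config$imageShape, collapse = "x"),
        nEpisodes(schedule))
    movie <- renderMovie(cells, schedule,
                         backgroundLevel = config$backgroundLevel,
                         backgroundDriftAmplitude = config$backgroundDriftAmplitude,
                         driftPeriodS = config$driftPeriodS,
                         noiseSd = config$noiseSd, tauS = config$tauS,
                         seed = config$seed + 1L)
    rois <- roiSetFromCells(cells, config$annulusGapPx, config$annulusWidthPx)

    issues <- validateInputs(movie, rois, schedule)
    if (any(issues$level == "error"))
        stop("stage validate: ", paste(issues$message[issues$level == "error"],
                                       collapse = "; "))

    corrected <- annulusCorrect(movie, rois)
    dff <- computeDff(corrected, schedule)
    log("extract", "%d traces x %d frames", nrow(dff), ncol(dff))

    responders <- callResponders(dff, schedule, config$thresholdPct)
    flags <- flagExclusions(dff, responders, rois, schedule,
                            config$spontaneousConsecFrames,
                            config$persistentFrac)
    classification <- classifyCells(responders, flags, schedule)
    counts <- table(classification$category)
    log("classify", "excluded %d of %d cells; %d pooled responders",
        sum(counts[grepl("^EXCLUDED", names(counts))]),
        nrow(classification),
        sum(counts[.INCLUDED_CATEGORIES]))
    proportions <- responderProportions(classification,
                                        group = paste0("seed", config$seed))

    sdExternal <- sdMap(movie, schedule, "EXTERNAL")
    sdInternal <- sdMap(movie, schedule, "INTERNAL")
    layout <- sortHeatmap(dff, classification)

    files <- c(classification = file.path(outDir, "classification.csv"),
               responders = file.path(outDir, "responders.csv"),
               proportions = file.path(outDir, "proportions.csv"),
               sdExternal = file.path(outDir, "sd_external.tif"),
               sdInternal = file.path(outDir, "sd_internal.tif"),
               layout = file.path(outDir, "heatmap_layout.csv"),
               schedule = file.path(outDir, "schedule.json"),
               groundTruth = file.path(outDir, "ground_truth.json"),
               config = file.path(outDir, "config.yaml"))
    utils::write.csv(classification, files["classification"], row.names = FALSE)
    utils::write.csv(responderCalls(responders), files["responders"],
                     row.names = FALSE)
    utils::write.csv(data.frame(category = names(categoryCounts(proportions)),
                                count = as.integer(categoryCounts(proportions)),
                                percent = as.numeric(categoryPercentages(proportions))),
                     files["proportions"], row.names = FALSE)
    writeSdMapTIFF(sdExternal, files["sdExternal"])
    writeSdMapTIFF(sdInternal, files["sdInternal"])
    utils::write.csv(layout, files["layout"], row.names = FALSE)
    writeScheduleJSON(schedule, files["schedule"])
    writeGroundTruthJSON(cells, files["groundTruth"])
    writePipelineConfig(config, files["config"])

    manifest <- list(
        package = "drgCalcium",
        packageVersion = as.character(utils::packageVersion("drgCalcium")),
        rVersion = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        configHash = unname(tools::md5sum(files[["config"]])),
        fileHashes = as.list(stats::setNames(
            unname(tools::md5sum(unname(files))),
            basename(unname(files)))))
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files["manifest"] <- manifestPath

    invisible(list(schedule = schedule, cells = cells, movie = movie,
                   rois = rois, corrected = corrected, dff = dff,
                   responders = responders, flags = flags,
                   classification = classification,
                   proportions = proportions,
                   sdExternal = sdExternal, sdInternal = sdInternal,
                   layout = layout, files = files))
}
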