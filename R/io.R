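## TIFF pages are stored normalized to [0, 1]; the intensity scale and the
## acquisition metadata travel in a small JSON sidecar (<path>.json).
.sidecarPath <- function(path) paste0(path, ".json")

#' Write a movie stack as multi-page 32-bit TIFF
#'
#' One concatenated stack per file. Pages are stored normalized to the
#' stack maximum; the scale, frame rate and episode boundaries are written
#' to a JSON sidecar (\code{<path>.json}) so the stack is self-describing.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param path output .tif path.
#' @return the path, invisibly.
#' @export
writeMovieTIFF <- function(movie, path) {
    d <- dim(movie@data)
    scale <- max(movie@data, 1e-12)
    pages <- lapply(seq_len(d[3L]), function(t) movie@data[, , t] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    jsonlite::write_json(
        list(scale = scale, frameRateHz = movie@frameRateHz,
             episodeBoundaries = movie@episodeBoundaries),
        .sidecarPath(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a multi-page TIFF movie stack
#'
#' Uses the JSON sidecar written by [writeMovieTIFF()] when present;
#' otherwise the scale defaults to 1 and frame rate / boundaries must be
#' supplied.
#'
#' @param path .tif path (single- or multi-page).
#' @param frameRateHz frames per second of the recording (ignored when a
#'   sidecar is present).
#' @param episodeBoundaries 1-based episode start frames (ignored when a
#'   sidecar is present).
#' @return a \linkS4class{MovieStack}.
#' @export
readMovieTIFF <- function(path, frameRateHz = NULL, episodeBoundaries = 1L) {
    scale <- 1
    sc <- .sidecarPath(path)
    if (file.exists(sc)) {
        meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
        scale <- meta$scale
        frameRateHz <- meta$frameRateHz
        episodeBoundaries <- meta$episodeBoundaries
    }
    if (is.null(frameRateHz))
        stop("frameRateHz required when no sidecar is present for ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    arr <- array(unlist(pages),
                 dim = c(dim(pages[[1L]])[1:2], length(pages))) * scale
    movieStack(arr, frameRateHz, episodeBoundaries)
}

#' Write / read an ROI label image as TIFF
#'
#' Labels are stored as 16-bit grayscale (exact for up to 65535 ROIs) and
#' rounded back to integers on read.
#'
#' @param rois a \linkS4class{RoiSet}.
#' @param path .tif path.
#' @return the path, invisibly.
#' @export
writeLabelTIFF <- function(rois, path) {
    if (max(rois@labels) > 65535L)
        stop("more than 65535 labels cannot be stored as 16-bit TIFF")
    tiff::writeTIFF(rois@labels / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    invisible(path)
}

#' @rdname writeLabelTIFF
#' @param annulusGapPx,annulusWidthPx annulus geometry to attach.
#' @param overlapPairs optional overlap record (see \linkS4class{RoiSet}).
#' @export
readLabelTIFF <- function(path, annulusGapPx = 1, annulusWidthPx = 3,
                          overlapPairs = NULL) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    roiSet(round(img * 65535), annulusGapPx, annulusWidthPx, overlapPairs)
}

#' Serialize / parse an episode schedule as JSON
#'
#' @param schedule an \linkS4class{EpisodeSchedule}.
#' @param path output .json path.
#' @return \code{writeScheduleJSON}: the path, invisibly;
#'   \code{readScheduleJSON}: an \linkS4class{EpisodeSchedule}.
#' @export
writeScheduleJSON <- function(schedule, path) {
    jsonlite::write_json(
        list(frameRateHz = schedule@frameRateHz,
             episodes = schedule@episodes),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeScheduleJSON
#' @export
readScheduleJSON <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    ep <- as.data.frame(x$episodes)
    intCols <- c("nFrames", "baselineFrames", "onsetFrame", "offsetFrame",
                 "startFrame")
    ep[intCols] <- lapply(ep[intCols], as.integer)
    new("EpisodeSchedule", episodes = ep, frameRateHz = x$frameRateHz)
}

#' Export / import traces as long-format CSV
#'
#' Columns: cellId, episode, frame (session index), value. The stage and
#' frame rate travel in a header comment-free sidecar-less form: they are
#' arguments on read.
#'
#' @param traces a \linkS4class{TraceMatrix}.
#' @param path .csv path.
#' @return \code{writeTracesCSV}: the path, invisibly;
#'   \code{readTracesCSV}: a \linkS4class{TraceMatrix}.
#' @export
writeTracesCSV <- function(traces, path) {
    v <- traceValues(traces)
    df <- data.frame(cellId = rep(rowData(traces)$cellId, ncol(v)),
                     episode = rep(colData(traces)$episode, each = nrow(v)),
                     frame = rep(seq_len(ncol(v)), each = nrow(v)),
                     value = as.vector(v))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTracesCSV
#' @param stage trace stage of the stored values.
#' @param frameRateHz frames per second.
#' @export
readTracesCSV <- function(path, stage, frameRateHz) {
    df <- utils::read.csv(path)
    ids <- sort(unique(df$cellId))
    frames <- sort(unique(df$frame))
    v <- matrix(NA_real_, length(ids), length(frames))
    v[cbind(match(df$cellId, ids), match(df$frame, frames))] <- df$value
    epOfFrame <- df$episode[match(frames, df$frame)]
    bounds <- frames[!duplicated(epOfFrame)]
    .traceMatrix(v, stage, frameRateHz, bounds, cellIds = ids)
}

#' Write an SD activity map as 32-bit TIFF
#'
#' The image is stored normalized to its maximum; scale, site and
#' contributing episodes go to a JSON sidecar (\code{<path>.json}).
#'
#' @param map a \linkS4class{SpatialActivityMap}.
#' @param path .tif path.
#' @return the path, invisibly.
#' @export
writeSdMapTIFF <- function(map, path) {
    scale <- max(map@sdImage, 1e-12)
    tiff::writeTIFF(map@sdImage / scale, path, bits.per.sample = 32L,
                    compression = "none")
    jsonlite::write_json(
        list(scale = scale, pooledSite = map@pooledSite,
             episodes = map@episodes),
        .sidecarPath(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read an SD activity map written by [writeSdMapTIFF()]
#'
#' @param path .tif path with its JSON sidecar.
#' @return a \linkS4class{SpatialActivityMap}.
#' @export
readSdMapTIFF <- function(path) {
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    new("SpatialActivityMap", sdImage = img * meta$scale,
        pooledSite = meta$pooledSite, episodes = as.integer(meta$episodes))
}

## Ground-truth JSON: cells, classes, amplitudes, run-length-encoded masks.
.rleEncode <- function(idx) {
    idx <- sort(idx)
    breaks <- which(diff(idx) != 1L)
    starts <- idx[c(1L, breaks + 1L)]
    ends <- idx[c(breaks, length(idx))]
    list(start = starts, length = ends - starts + 1L)
}

#' Write synthetic ground truth as JSON
#'
#' Stores cell ids, planted classes, amplitudes, baseline levels and
#' run-length-encoded footprint masks.
#'
#' @param cells a \linkS4class{GroundTruthCells}.
#' @param path .json path.
#' @return the path, invisibly.
#' @export
writeGroundTruthJSON <- function(cells, path) {
    jsonlite::write_json(
        list(imageShape = cells@imageShape,
             info = cells@info,
             overlapPairs = cells@overlapPairs,
             footprintsRLE = lapply(cells@footprints, .rleEncode)),
        path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
    invisible(path)
}
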