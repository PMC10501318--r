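## Internal constructor: wrap a cells x frames matrix into a TraceMatrix.
.traceMatrix <- function(values, stage, frameRateHz, episodeBoundaries,
                         cellIds = seq_len(nrow(values)), extraMeta = list()) {
    total <- ncol(values)
    b <- as.integer(episodeBoundaries)
    episode <- findInterval(seq_len(total), b)
    cd <- DataFrame(frame = seq_len(total), episode = episode)
    rd <- DataFrame(cellId = as.integer(cellIds))
    dimnames(values) <- list(paste0("cell_", cellIds), NULL)
    se <- SummarizedExperiment(assays = list(traces = values),
                               rowData = rd, colData = cd)
    md <- c(list(frameRateHz = frameRateHz, episodeBoundaries = b), extraMeta)
    metadata(se) <- md
    new("TraceMatrix", se, stage = stage)
}

#' @rdname TraceMatrix-class
#' @export
setMethod("traceStage", "TraceMatrix", function(x) x@stage)

#' @rdname TraceMatrix-class
#' @export
setMethod("traceValues", "TraceMatrix", function(x) assay(x, "traces"))

#' @rdname TraceMatrix-class
#' @export
setMethod("frameRate", "TraceMatrix", function(x) metadata(x)$frameRateHz)

#' @rdname TraceMatrix-class
#' @export
setMethod("episodeBoundaries", "TraceMatrix",
          function(x) metadata(x)$episodeBoundaries)

setMethod("show", "TraceMatrix", function(object) {
    cat("TraceMatrix [", object@stage, "]: ", nrow(object), " cells x ",
        ncol(object), " frames, ", length(episodeBoundaries(object)),
        " episodes at ", frameRate(object), " Hz\n", sep = "")
    invisible(NULL)
})

## Footprint pixel indices per label, with empty-footprint checking.
.footprintIndices <- function(rois) {
    lab <- rois@labels
    n <- max(lab)
    if (n < 1L)
        stop("no ROIs: label image contains label 0 only")
    idx <- split(which(lab > 0), lab[lab > 0])
    out <- vector("list", n)
    out[as.integer(names(idx))] <- idx
    empty <- which(vapply(out, is.null, logical(1)))
    if (length(empty))
        stop("empty footprint for label(s): ", paste(empty, collapse = ", "))
    out
}

#' Extract raw per-cell fluorescence traces
#'
#' Reads out, for every ROI label, the mean pixel intensity over its
#' footprint at every frame of the movie.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param rois a \linkS4class{RoiSet} whose label image matches the movie
#'   frame shape.
#' @return a \linkS4class{TraceMatrix} at stage \code{RAW} (one row per
#'   label, in label order).
#' @export
extractTraces <- function(movie, rois) {
    stopifnot(is(movie, "MovieStack"), is(rois, "RoiSet"))
    d <- dim(movie@data)
    if (!identical(dim(rois@labels), d[1:2]))
        stop("label image shape (", paste(dim(rois@labels), collapse = "x"),
             ") does not match movie frames (", paste(d[1:2], collapse = "x"), ")")
    fp <- .footprintIndices(rois)
    m <- matrix(movie@data, nrow = d[1L] * d[2L], ncol = d[3L])
    values <- t(vapply(fp, function(idx) {
        if (length(idx) == 1L) m[idx, ] else colMeans(m[idx, , drop = FALSE])
    }, numeric(d[3L])))
    .traceMatrix(values, "RAW", movie@frameRateHz, movie@episodeBoundaries)
}

#' Annulus ("donut") pixel indices for every ROI
#'
#' For cell k the annulus is the set of pixels whose Euclidean distance d
#' to the cell's footprint satisfies \code{gap < d <= gap + width}, minus
#' every labeled pixel of any cell (so neighbouring somata never
#' contaminate a background estimate).
#'
#' @param rois a \linkS4class{RoiSet}.
#' @return list of integer vectors of linear pixel indices, one per label.
#' @export
annulusIndices <- function(rois) {
    lab <- rois@labels
    H <- nrow(lab); W <- ncol(lab)
    gap <- rois@annulusGapPx
    width <- rois@annulusWidthPx
    reach <- ceiling(gap + width)
    anyLabel <- lab > 0
    fp <- .footprintIndices(rois)
    lapply(seq_along(fp), function(k) {
        idx <- fp[[k]]
        fr <- ((idx - 1L) %% H) + 1L
        fc <- ((idx - 1L) %/% H) + 1L
        rows <- seq.int(max(1L, min(fr) - reach), min(H, max(fr) + reach))
        cols <- seq.int(max(1L, min(fc) - reach), min(W, max(fc) + reach))
        cand <- expand.grid(row = rows, col = cols)
        # min distance from each candidate pixel to the footprint
        d2 <- outer(cand$row, fr, "-")^2 + outer(cand$col, fc, "-")^2
        dmin <- sqrt(.rowMins(d2))
        keep <- dmin > gap & dmin <= gap + width
        ann <- (cand$col[keep] - 1L) * H + cand$row[keep]
        ann <- ann[!anyLabel[ann]]
        if (!length(ann))
            stop("annulus empty for label ", k,
                 " (crowded field or image edge); widen annulusWidthPx or",
                 " reduce annulusGapPx")
        as.integer(ann)
    })
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Annulus background correction
#'
#' Removes contaminant signal (out-of-focus tissue, neighbouring cells) by
#' subtracting, frame by frame, the mean fluorescence of a donut-shaped
#' area surrounding each ROI from the ROI's raw trace. For a spatially
#' uniform additive background the correction is exact.
#'
#' @inheritParams extractTraces
#' @return a \linkS4class{TraceMatrix} at stage \code{CORRECTED}.
#' @export
annulusCorrect <- function(movie, rois) {
    raw <- extractTraces(movie, rois)
    ann <- annulusIndices(rois)
    d <- dim(movie@data)
    m <- matrix(movie@data, nrow = d[1L] * d[2L], ncol = d[3L])
    annMeans <- t(vapply(ann, function(idx) {
        if (length(idx) == 1L) m[idx, ] else colMeans(m[idx, , drop = FALSE])
    }, numeric(d[3L])))
    values <- traceValues(raw) - annMeans
    .traceMatrix(values, "CORRECTED", movie@frameRateHz,
                 movie@episodeBoundaries)
}

#' Percent dF/F normalization
#'
#' Converts fluorescence traces to percent dF/F episode by episode:
#' \code{100 * (F - F0) / F0} with \code{F0} the mean fluorescence over
#' that episode's baseline window, re-estimated per episode so that
#' concatenated episodes remain individually baseline-centred. A
#' cell-episode whose baseline mean is not positive cannot be normalized;
#' its frames are set to \code{NA}, the cell-episode is recorded in
#' \code{metadata(x)$unusable}, and a warning is raised (never silently
#' zeroed).
#'
#' @param traces a \linkS4class{TraceMatrix} at stage \code{RAW} or
#'   \code{CORRECTED}.
#' @param schedule the \linkS4class{EpisodeSchedule} defining baseline
#'   windows; total frames must match the trace matrix.
#' @return a \linkS4class{TraceMatrix} at stage \code{DFF} (percent units);
#'   the per-episode baseline means are kept in
#'   \code{metadata(x)$baselineF0} (cells x episodes), which lets the
#'   persistence exclusion judge later frames against a cell's
#'   pre-stimulus baseline even though each episode is re-centred.
#' @export
computeDff <- function(traces, schedule) {
    stopifnot(is(traces, "TraceMatrix"), is(schedule, "EpisodeSchedule"))
    if (traces@stage == "DFF")
        stop("traces are already at stage DFF")
    if (sessionFrames(schedule) != ncol(traces))
        stop("schedule frame count (", sessionFrames(schedule),
             ") does not match traces (", ncol(traces), ")")
    v <- traceValues(traces)
    out <- matrix(NA_real_, nrow(v), ncol(v))
    f0mat <- matrix(NA_real_, nrow(v), nEpisodes(schedule))
    unusable <- list()
    for (e in seq_len(nEpisodes(schedule))) {
        cols <- .episodeFrameRange(schedule, e)
        bcols <- .baselineFrameRange(schedule, e)
        f0 <- rowMeans(v[, bcols, drop = FALSE])
        f0mat[, e] <- f0
        bad <- f0 <= 0
        ok <- which(!bad)
        out[ok, cols] <- 100 * (v[ok, cols, drop = FALSE] - f0[ok]) / f0[ok]
        if (any(bad))
            unusable[[length(unusable) + 1L]] <-
                data.frame(cellId = which(bad), episode = e)
    }
    unusable <- if (length(unusable)) do.call(rbind, unusable) else
        data.frame(cellId = integer(0), episode = integer(0))
    if (nrow(unusable))
        warning("baseline F0 <= 0; flagged unusable (NA) for ",
                nrow(unusable), " cell-episode(s): cells ",
                paste(unique(unusable$cellId), collapse = ", "))
    .traceMatrix(out, "DFF", frameRate(traces), episodeBoundaries(traces),
                 cellIds = rowData(traces)$cellId,
                 extraMeta = list(unusable = unusable, baselineF0 = f0mat))
}

#' Concatenate per-episode trace matrices
#'
#' Joins single-episode (or partial-session) trace matrices in protocol
#' order into one session matrix whose episode boundaries are recorded, so
#' each row tracks the same neuron across all episodes. Inter-episode
#' pauses are boundary markers, not data frames.
#'
#' @param traceList list of \linkS4class{TraceMatrix} objects sharing cell
#'   set, stage and frame rate.
#' @return a \linkS4class{TraceMatrix} covering all frames.
#' @export
concatenateEpisodes <- function(traceList) {
    stopifnot(length(traceList) >= 1L,
              all(vapply(traceList, is, logical(1), "TraceMatrix")))
    if (length(traceList) == 1L) return(traceList[[1L]])
    stages <- vapply(traceList, function(x) x@stage, character(1))
    if (length(unique(stages)) != 1L)
        stop("all matrices must share one stage; got: ",
             paste(unique(stages), collapse = ", "))
    ncells <- vapply(traceList, nrow, integer(1))
    if (length(unique(ncells)) != 1L)
        stop("mismatched cell counts across episodes: ",
             paste(ncells, collapse = ", "))
    ids <- lapply(traceList, function(x) rowData(x)$cellId)
    if (!all(vapply(ids, identical, logical(1), ids[[1L]])))
        stop("cell ids differ across episodes")
    rates <- vapply(traceList, frameRate, numeric(1))
    if (length(unique(rates)) != 1L)
        stop("frame rates differ across episodes")
    nf <- vapply(traceList, ncol, integer(1))
    values <- do.call(cbind, lapply(traceList, traceValues))
    bounds <- cumsum(c(1L, nf[-length(nf)]))
    .traceMatrix(values, stages[1L], rates[1L], bounds, cellIds = ids[[1L]])
}
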