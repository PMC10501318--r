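#' Pixelwise standard-deviation spatial activity map
#'
#' Computes, for every pixel, the population standard deviation of its
#' intensity over all frames of all episodes of the requested stimulation
#' site (external or internal), pooled. Pixels with the most fluorescence
#' change during those stimuli — active somata — appear bright.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param schedule the matching \linkS4class{EpisodeSchedule}.
#' @param site \code{"EXTERNAL"} or \code{"INTERNAL"}.
#' @param episodesUsed optional integer subset of episode indices (must be
#'   of the requested site); default pools every episode of the site.
#' @return a \linkS4class{SpatialActivityMap}.
#' @export
sdMap <- function(movie, schedule, site = c("EXTERNAL", "INTERNAL"),
                  episodesUsed = NULL) {
    site <- match.arg(site)
    stopifnot(is(movie, "MovieStack"), is(schedule, "EpisodeSchedule"))
    ep <- episodes(schedule)
    eps <- which(ep$site == site)
    if (!is.null(episodesUsed)) {
        if (!all(episodesUsed %in% eps))
            stop("episodesUsed must index episodes of site ", site)
        eps <- as.integer(episodesUsed)
    }
    if (!length(eps))
        stop("no ", site, " episodes in the schedule")
    frames <- unlist(lapply(eps, .episodeFrameRange, schedule = schedule))
    d <- dim(movie@data)
    m <- matrix(movie@data, nrow = d[1L] * d[2L], ncol = d[3L])[, frames,
                                                               drop = FALSE]
    mu <- rowMeans(m)
    sdv <- sqrt(rowMeans((m - mu)^2))   # population (ddof = 0) SD
    new("SpatialActivityMap",
        sdImage = matrix(sdv, d[1L], d[2L]),
        pooledSite = site, episodes = eps)
}

#' @rdname SpatialActivityMap-class
#' @export
setMethod("sdImage", "SpatialActivityMap", function(x) x@sdImage)

setMethod("show", "SpatialActivityMap", function(object) {
    cat("SpatialActivityMap [", object@pooledSite, "]: ",
        paste(dim(object@sdImage), collapse = "x"), " px, pooled over ",
        length(object@episodes), " episode(s)\n", sep = "")
    invisible(NULL)
})

#' Category-sorted heatmap layout
#'
#' Orders included responder cells for heatmap display: category blocks in
#' the fixed order internal, external-gentle, external-noxious; within each
#' block rows in descending session-maximum dF/F, ties broken by ascending
#' cell id. Excluded cells and non-responders are omitted. Episode
#' boundaries (the recording pauses between episodes) are carried as gap
#' markers.
#'
#' @param dff a \linkS4class{TraceMatrix} at stage \code{DFF}.
#' @param classifications data.frame from [classifyCells()].
#' @return data.frame with columns \code{row}, \code{cellId},
#'   \code{category}, \code{peakDff}; attributes
#'   \code{episodeBoundaries} (gap-marker frames) and
#'   \code{blockBoundaries} (first row of each category block).
#' @export
sortHeatmap <- function(dff, classifications) {
    stopifnot(is(dff, "TraceMatrix"))
    if (dff@stage != "DFF")
        stop("sortHeatmap needs a DFF-stage TraceMatrix")
    ids <- rowData(dff)$cellId
    if (!all(ids %in% classifications$cellId))
        stop("classification missing for some trace rows")
    cls <- classifications[match(ids, classifications$cellId), ]
    v <- traceValues(dff)
    peak <- apply(v, 1L, function(x)
        if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    keep <- cls$category %in% .INCLUDED_CATEGORIES
    df <- data.frame(cellId = ids[keep],
                     category = factor(as.character(cls$category[keep]),
                                       levels = .INCLUDED_CATEGORIES),
                     peakDff = peak[keep])
    df <- df[order(df$category, -df$peakDff, df$cellId), ]
    df <- data.frame(row = seq_len(nrow(df)), df, row.names = NULL)
    blockStarts <- match(.INCLUDED_CATEGORIES, as.character(df$category))
    attr(df, "episodeBoundaries") <- episodeBoundaries(dff)
    attr(df, "blockBoundaries") <- blockStarts
    df
}

#' Plot a category-sorted dF/F heatmap
#'
#' Base-graphics rendering of the sorted heatmap with white gap lines at
#' episode boundaries (the inter-episode recording pauses) and horizontal
#' separators between category blocks.
#'
#' @param dff a \linkS4class{TraceMatrix} at stage \code{DFF}.
#' @param layout data.frame from [sortHeatmap()].
#' @param zlim dF/F colour range; defaults to the data range.
#' @param main plot title.
#' @return the layout, invisibly.
#' @export
plotResponseHeatmap <- function(dff, layout, zlim = NULL,
                                main = "dF/F by responder category") {
    v <- traceValues(dff)[match(layout$cellId, rowData(dff)$cellId), ,
                          drop = FALSE]
    if (is.null(zlim))
        zlim <- range(v, na.rm = TRUE, finite = TRUE)
    v[v < zlim[1L]] <- zlim[1L]; v[v > zlim[2L]] <- zlim[2L]
    pal <- grDevices::hcl.colors(64, "Inferno")
    graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)),
                    z = t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                    zlim = zlim, col = pal, xlab = "frame", ylab = "cell",
                    main = main, useRaster = TRUE)
    for (b in attr(layout, "episodeBoundaries")[-1L])
        graphics::abline(v = b - 0.5, col = "white", lwd = 2)
    bb <- attr(layout, "blockBoundaries")
    for (b in bb[!is.na(bb)][-1L])
        graphics::abline(h = nrow(v) - b + 1.5, col = "white", lwd = 1)
    invisible(layout)
}

#' Render an SD map to PNG
#'
#' @param map a \linkS4class{SpatialActivityMap}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plotSdMap <- function(map, path) {
    img <- sdImage(map)
    rng <- range(img)
    scaled <- if (diff(rng) > 0) (img - rng[1L]) / diff(rng) else img * 0
    grDevices::png(path, width = ncol(img), height = nrow(img))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({graphics::par(op); grDevices::dev.off()}, add = TRUE)
    graphics::image(t(scaled[rev(seq_len(nrow(scaled))), , drop = FALSE]),
                    col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                    useRaster = TRUE)
    invisible(path)
}
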