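#' Call per-episode responders at a strict dF/F threshold
#'
#' For every cell and episode, takes the peak percent dF/F over the
#' response window (stimulus onset to episode end) and calls the cell a
#' responder for that episode when the peak strictly exceeds the activation
#' threshold (default 5 percent dF/F; a peak of exactly 5 is not a
#' response).
#'
#' @param dff a \linkS4class{TraceMatrix} at stage \code{DFF}.
#' @param schedule the matching \linkS4class{EpisodeSchedule}.
#' @param thresholdPct activation threshold, percent dF/F (> 0).
#' @return a \linkS4class{ResponderTable}.
#' @export
callResponders <- function(dff, schedule, thresholdPct = 5) {
    stopifnot(is(dff, "TraceMatrix"), is(schedule, "EpisodeSchedule"))
    if (dff@stage != "DFF")
        stop("callResponders needs a DFF-stage TraceMatrix, got ", dff@stage)
    if (thresholdPct <= 0) stop("thresholdPct must be > 0")
    if (sessionFrames(schedule) != ncol(dff))
        stop("schedule frame count (", sessionFrames(schedule),
             ") does not match traces (", ncol(dff), ")")
    v <- traceValues(dff)
    ep <- episodes(schedule)
    ids <- rowData(dff)$cellId
    calls <- do.call(rbind, lapply(seq_len(nrow(ep)), function(e) {
        cols <- .responseFrameRange(schedule, e)
        peak <- apply(v[, cols, drop = FALSE], 1L, function(x)
            if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
        data.frame(cellId = ids, episode = e,
                   stimulus = ep$stimulus[e], site = ep$site[e],
                   peakDff = peak, isResponder = peak > thresholdPct,
                   stringsAsFactors = FALSE)
    }))
    rownames(calls) <- NULL
    new("ResponderTable", calls = calls, thresholdPct = thresholdPct)
}

#' @rdname ResponderTable-class
#' @export
setMethod("responderCalls", "ResponderTable", function(x) x@calls)

#' @rdname ResponderTable-class
#' @export
setMethod("responderThreshold", "ResponderTable", function(x) x@thresholdPct)

setMethod("show", "ResponderTable", function(object) {
    calls <- object@calls
    cat("ResponderTable:", length(unique(calls$cellId)), "cells x",
        length(unique(calls$episode)), "episodes; threshold dF/F >",
        object@thresholdPct, "%\n")
    cat("responding cell-episodes:", sum(calls$isResponder, na.rm = TRUE), "\n")
    invisible(NULL)
})

.maxRunTrue <- function(x) {
    x[is.na(x)] <- FALSE
    if (!any(x)) return(0L)
    r <- rle(x)
    max(r$lengths[r$values])
}

#' Flag cells for exclusion
#'
#' Applies the three exclusion rules ahead of categorisation:
#' \describe{
#'   \item{SPONTANEOUS}{dF/F exceeds the activation threshold for at least
#'     \code{spontaneousConsecFrames} consecutive baseline frames. Only
#'     baselines of episodes up to and including the cell's first
#'     responding episode are examined, so post-stimulus elevation carried
#'     into later baselines is attributed to persistence, not spontaneous
#'     activity.}
#'   \item{PERSISTENT}{after the cell's first responding episode, the cell
#'     stays above the threshold in at least \code{persistentFrac} of all
#'     subsequent frames through the end of the session. Because dF/F is
#'     re-baselined per episode (which hides a sustained plateau), the
#'     comparison is made against the baseline of the first responding
#'     episode, reconstructed from \code{metadata(dff)$baselineF0}; when
#'     that metadata is absent (e.g. traces imported from CSV) the
#'     per-episode dF/F values are used as-is.}
#'   \item{OVERLAP}{the cell's footprint shares at least one pixel with
#'     another ROI, per the label-image construction record.}
#' }
#'
#' @param dff a \linkS4class{TraceMatrix} at stage \code{DFF}.
#' @param responders the matching \linkS4class{ResponderTable}.
#' @param rois the \linkS4class{RoiSet} (source of the overlap record).
#' @param schedule the \linkS4class{EpisodeSchedule}.
#' @param spontaneousConsecFrames run length of supra-threshold baseline
#'   frames that flags spontaneous activity (default 3 frames = 0.6 s at
#'   5 Hz).
#' @param persistentFrac fraction of post-response frames above threshold
#'   that flags persistent activation (default 0.8).
#' @return data.frame with columns \code{cellId}, \code{spontaneous},
#'   \code{persistent}, \code{overlap}.
#' @export
flagExclusions <- function(dff, responders, rois, schedule,
                           spontaneousConsecFrames = 3,
                           persistentFrac = 0.8) {
    stopifnot(is(dff, "TraceMatrix"), is(responders, "ResponderTable"))
    v <- traceValues(dff)
    thr <- responders@thresholdPct
    calls <- responders@calls
    ids <- rowData(dff)$cellId
    nEp <- nEpisodes(schedule)
    total <- ncol(v)
    ep <- episodes(schedule)

    spont <- persist <- logical(length(ids))
    for (i in seq_along(ids)) {
        cellCalls <- calls[calls$cellId == ids[i], ]
        cellCalls <- cellCalls[order(cellCalls$episode), ]
        respEp <- cellCalls$episode[which(cellCalls$isResponder %in% TRUE)]
        firstResp <- if (length(respEp)) min(respEp) else NA_integer_
        lastBaselineEp <- if (is.na(firstResp)) nEp else firstResp
        for (e in seq_len(lastBaselineEp)) {
            b <- v[i, .baselineFrameRange(schedule, e)] > thr
            if (.maxRunTrue(b) >= spontaneousConsecFrames) {
                spont[i] <- TRUE
                break
            }
        }
        if (!is.na(firstResp)) {
            afterStart <- ep$startFrame[firstResp] + ep$nFrames[firstResp]
            if (afterStart <= total) {
                after <- afterStart:total
                f0mat <- metadata(dff)$baselineF0
                if (!is.null(f0mat) && f0mat[i, firstResp] > 0) {
                    # re-reference later frames to the pre-stimulus baseline
                    # of the first responding episode
                    epOfFrame <- findInterval(after, ep$startFrame)
                    f <- f0mat[i, epOfFrame] * (1 + v[i, after] / 100)
                    rel <- 100 * (f - f0mat[i, firstResp]) / f0mat[i, firstResp]
                } else {
                    rel <- v[i, after]
                }
                frac <- mean(rel > thr, na.rm = TRUE)
                persist[i] <- is.finite(frac) && frac >= persistentFrac
            }
        }
    }
    overlap <- ids %in% as.vector(rois@overlapPairs)
    data.frame(cellId = ids, spontaneous = spont, persistent = persist,
               overlap = overlap)
}

#' Assign each cell to a responder category
#'
#' Categorises cells with the fixed precedence: exclusion flags first
#' (overlapping ROI, then spontaneous baseline activity, then persistent
#' activation), then cells responding to at least one internal and one
#' external episode are excluded as mixed responders. Remaining responders
#' are \code{INTERNAL} if all responding episodes are colonic,
#' \code{EXTERNAL_GENTLE} if any puff or skin-brush response (a pinch
#' response in addition does not change the category), and
#' \code{EXTERNAL_NOXIOUS} when the pinch is the only external response.
#' Cells with no responding episode are \code{NONRESPONDER}.
#'
#' @param responders a \linkS4class{ResponderTable}.
#' @param exclusionFlags data.frame from [flagExclusions()].
#' @param schedule the \linkS4class{EpisodeSchedule}.
#' @return data.frame with columns \code{cellId}, \code{category} (factor
#'   over the eight categories), \code{nRespondingEpisodes}.
#' @export
classifyCells <- function(responders, exclusionFlags, schedule) {
    stopifnot(is(responders, "ResponderTable"))
    ep <- episodes(schedule)
    if (!all(ep$site %in% c("EXTERNAL", "INTERNAL")))
        stop("config error: unknown stimulus site in schedule")
    calls <- responders@calls
    ids <- sort(unique(calls$cellId))
    if (!all(ids %in% exclusionFlags$cellId))
        stop("exclusion flags missing for some cells")
    flags <- exclusionFlags[match(ids, exclusionFlags$cellId), ]
    gentleStimuli <- c("PUFF", "SKIN_BRUSH")

    category <- character(length(ids))
    nResp <- integer(length(ids))
    for (i in seq_along(ids)) {
        cc <- calls[calls$cellId == ids[i] & calls$isResponder %in% TRUE, ]
        nResp[i] <- nrow(cc)
        category[i] <- if (flags$overlap[i]) "EXCLUDED_OVERLAP"
        else if (flags$spontaneous[i]) "EXCLUDED_SPONTANEOUS"
        else if (flags$persistent[i]) "EXCLUDED_PERSISTENT"
        else if (nrow(cc) == 0L) "NONRESPONDER"
        else if (any(cc$site == "INTERNAL") && any(cc$site == "EXTERNAL"))
            "EXCLUDED_BOTH"
        else if (all(cc$site == "INTERNAL")) "INTERNAL"
        else if (any(cc$stimulus %in% gentleStimuli)) "EXTERNAL_GENTLE"
        else "EXTERNAL_NOXIOUS"
    }
    data.frame(cellId = ids,
               category = factor(category, levels = .CATEGORIES),
               nRespondingEpisodes = nResp)
}

#' Pool responder proportions
#'
#' Pools all included responders (internal, external-gentle,
#' external-noxious) as 100 percent and reports each category's share.
#' Excluded cells and non-responders contribute to neither numerator nor
#' denominator.
#'
#' @param classifications data.frame from [classifyCells()].
#' @param group free-text group label carried into the summary.
#' @return a \linkS4class{ProportionSummary}.
#' @export
responderProportions <- function(classifications, group = "group") {
    counts <- table(factor(classifications$category,
                           levels = .INCLUDED_CATEGORIES))
    counts <- stats::setNames(as.integer(counts), .INCLUDED_CATEGORIES)
    if (sum(counts) == 0L)
        stop("empty denominator: no included responders to pool")
    new("ProportionSummary", counts = counts, group = group)
}

#' @rdname ProportionSummary-class
#' @export
setMethod("categoryCounts", "ProportionSummary", function(x) x@counts)

#' @rdname ProportionSummary-class
#' @export
setMethod("categoryPercentages", "ProportionSummary",
          function(x) 100 * x@counts / sum(x@counts))

setMethod("show", "ProportionSummary", function(object) {
    cat("ProportionSummary [", object@group, "]: ",
        sum(object@counts), " pooled responders\n", sep = "")
    pct <- categoryPercentages(object)
    for (nm in names(pct))
        cat(sprintf("  %-17s %4d (%.1f%%)\n", nm, object@counts[nm], pct[nm]))
    invisible(NULL)
})

#' Compare responder proportions between two groups
#'
#' Pearson chi-square test (no continuity correction) on the 2-group x
#' 3-category contingency table of included-responder counts. A category
#' empty in both groups is dropped with a warning and the degrees of
#' freedom reduced accordingly; the full 2 x 3 table has 2 degrees of
#' freedom.
#'
#' @param summaryA,summaryB \linkS4class{ProportionSummary} objects.
#' @return list with \code{chi2}, \code{dof}, \code{p}, and the tested
#'   count \code{table}.
#' @export
compareGroups <- function(summaryA, summaryB) {
    stopifnot(is(summaryA, "ProportionSummary"),
              is(summaryB, "ProportionSummary"))
    tab <- rbind(summaryA@counts, summaryB@counts)
    rownames(tab) <- c(summaryA@group, summaryB@group)
    empty <- colSums(tab) == 0
    if (any(empty)) {
        warning("category empty in both groups, dropped: ",
                paste(colnames(tab)[empty], collapse = ", "))
        tab <- tab[, !empty, drop = FALSE]
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chi2 = unname(ht$statistic), dof = unname(ht$parameter),
         p = unname(ht$p.value), table = tab)
}
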