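#' Planted response classes
#'
#' Ground-truth classes a synthetic cell can be planted with, mirroring the
#' downstream responder categories and exclusion cases: cells responding to
#' internal (colonic) stimuli only, to gentle external stimuli (puff and
#' skin brush), to the noxious pinch only, to both sites (which the
#' classifier must exclude), silent cells, cells with spontaneous baseline
#' activity, and cells that stay active after their first response.
#'
#' @return character vector of class names.
#' @export
plantedClasses <- function() .CELL_CLASSES

.defaultCellCounts <- function() {
    # realistic session: a few tens of cells per field, most responders
    c(INTERNAL_ONLY = 6L, EXTERNAL_GENTLE = 6L, EXTERNAL_NOXIOUS_ONLY = 4L,
      BOTH = 2L, SILENT = 3L, SPONTANEOUS = 2L, PERSISTENT = 1L)
}

.diskIndices <- function(centerRow, centerCol, radius, imageShape) {
    r <- seq.int(max(1L, centerRow - radius), min(imageShape[1L], centerRow + radius))
    c0 <- seq.int(max(1L, centerCol - radius), min(imageShape[2L], centerCol + radius))
    grid <- expand.grid(row = r, col = c0)
    keep <- (grid$row - centerRow)^2 + (grid$col - centerCol)^2 <= radius^2
    grid <- grid[keep, , drop = FALSE]
    as.integer((grid$col - 1L) * imageShape[1L] + grid$row)
}

#' Generate a ground-truthed synthetic cell population
#'
#' Places disjoint disk footprints uniformly at random on the field and
#' assigns each cell a planted response class, a transient amplitude
#' (percent dF/F) and a baseline fluorescence level. With
#' \code{plantOverlap = TRUE} one extra pair of overlapping footprints is
#' planted and recorded, to exercise the overlapping-ROI exclusion rule.
#'
#' @param nPerClass named integer vector of cell counts per planted class
#'   (names from [plantedClasses()]); missing classes default to 0.
#' @param imageShape height/width of the field in pixels.
#' @param footprintRadius disk radius in pixels.
#' @param amplitudePct planted transient amplitude, percent dF/F.
#' @param baselineLevel baseline cell fluorescence in intensity units.
#' @param plantOverlap plant one overlapping ROI pair (two extra cells).
#' @param seed integer seed for reproducible placement; \code{NULL} leaves
#'   the RNG state alone.
#' @return a \linkS4class{GroundTruthCells}.
#' @examples
#' cells <- generateCells(c(INTERNAL_ONLY = 3), imageShape = c(64, 64), seed = 1)
#' cellInfo(cells)
#' @export
generateCells <- function(nPerClass = .defaultCellCounts(),
                          imageShape = c(256L, 256L),
                          footprintRadius = 4,
                          amplitudePct = 20,
                          baselineLevel = 100,
                          plantOverlap = FALSE,
                          seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    imageShape <- as.integer(imageShape)
    counts <- integer(length(.CELL_CLASSES))
    names(counts) <- .CELL_CLASSES
    if (length(nPerClass)) {
        unknown <- setdiff(names(nPerClass), .CELL_CLASSES)
        if (length(unknown))
            stop("unknown planted class(es): ", paste(unknown, collapse = ", "))
        if (any(nPerClass < 0)) stop("cell counts must be >= 0")
        counts[names(nPerClass)] <- as.integer(nPerClass)
    }
    classes <- rep(names(counts), counts)
    n <- length(classes)
    r <- footprintRadius
    minSep <- 2 * r + 2     # disjoint footprints with one clear pixel between
    lo <- r + 1L
    hiR <- imageShape[1L] - r
    hiC <- imageShape[2L] - r
    if (n > 0 && (hiR < lo || hiC < lo))
        stop("placement error: image too small for footprint radius ", r)

    # rejection sampling with full restarts when a partial placement jams
    centers <- matrix(numeric(0), ncol = 2)
    maxTries <- 500L * max(n, 1L)
    restarts <- 0L
    tries <- 0L
    while (nrow(centers) < n) {
        tries <- tries + 1L
        if (tries > maxTries) {
            restarts <- restarts + 1L
            if (restarts > 50L)
                stop("placement error: could not place ", n,
                     " cells of radius ", r, " in a ", imageShape[1L], "x",
                     imageShape[2L], " field without unplanted overlap")
            centers <- matrix(numeric(0), ncol = 2)
            tries <- 0L
        }
        cand <- c(sample.int(hiR - lo + 1L, 1L) + lo - 1L,
                  sample.int(hiC - lo + 1L, 1L) + lo - 1L)
        if (nrow(centers) == 0 ||
            all((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2 >=
                minSep^2))
            centers <- rbind(centers, cand)
    }

    overlap <- matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("a", "b")))
    if (plantOverlap) {
        # a pair whose centers sit one radius apart: footprints share pixels
        placed <- FALSE
        for (i in seq_len(maxTries)) {
            cand <- c(sample.int(hiR - lo + 1L, 1L) + lo - 1L,
                      sample.int(hiC - lo + 1L, 1L) + lo - 1L)
            mate <- cand + c(0L, as.integer(r))
            if (mate[2L] > hiC) next
            ok <- nrow(centers) == 0 ||
                (all((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2 >= minSep^2) &&
                 all((centers[, 1L] - mate[1L])^2 + (centers[, 2L] - mate[2L])^2 >= minSep^2))
            if (ok) {
                centers <- rbind(centers, cand, mate)
                classes <- c(classes, "INTERNAL_ONLY", "EXTERNAL_GENTLE")
                overlap <- rbind(overlap, c(length(classes) - 1L, length(classes)))
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("placement error: no room for the planted overlapping pair")
        n <- n + 2L
    }

    fp <- lapply(seq_len(n), function(i)
        .diskIndices(centers[i, 1L], centers[i, 2L], r, imageShape))
    info <- data.frame(
        cellId = seq_len(n),
        class = classes,
        amplitudePct = rep_len(amplitudePct, n),
        baselineLevel = rep_len(baselineLevel, n),
        centerRow = as.integer(centers[, 1L]),
        centerCol = as.integer(centers[, 2L]),
        radius = rep(r, n),
        stringsAsFactors = FALSE)
    if (n == 0)
        info <- info[0, , drop = FALSE]
    new("GroundTruthCells", info = info, footprints = fp,
        imageShape = imageShape, overlapPairs = overlap)
}

#' @rdname GroundTruthCells-class
#' @export
setMethod("cellInfo", "GroundTruthCells", function(x) x@info)

#' @rdname GroundTruthCells-class
#' @export
setMethod("footprints", "GroundTruthCells", function(x) x@footprints)

#' @rdname GroundTruthCells-class
#' @export
setMethod("overlapPairs", "GroundTruthCells", function(x) x@overlapPairs)

setMethod("show", "GroundTruthCells", function(object) {
    cat("GroundTruthCells:", nrow(object@info), "cells on a",
        paste(object@imageShape, collapse = "x"), "field\n")
    if (nrow(object@info))
        print(table(object@info$class))
    if (nrow(object@overlapPairs))
        cat("planted overlapping pairs:", nrow(object@overlapPairs), "\n")
    invisible(NULL)
})

#' Build a RoiSet label image from synthetic cells
#'
#' Rasterizes the footprints into an integer label image (later cells win
#' contested pixels of a planted overlap) and attaches annulus geometry and
#' the overlap record.
#'
#' @param cells a \linkS4class{GroundTruthCells}.
#' @param annulusGapPx gap between footprint and annulus, pixels.
#' @param annulusWidthPx annulus radial width, pixels.
#' @return a \linkS4class{RoiSet}.
#' @export
roiSetFromCells <- function(cells, annulusGapPx = 1, annulusWidthPx = 3) {
    shape <- cells@imageShape
    lab <- matrix(0L, shape[1L], shape[2L])
    for (i in seq_along(cells@footprints))
        lab[cells@footprints[[i]]] <- i
    new("RoiSet", labels = lab, annulusGapPx = annulusGapPx,
        annulusWidthPx = annulusWidthPx, overlapPairs = cells@overlapPairs)
}

#' Construct a RoiSet from a label image
#'
#' @param labels integer matrix (0 background, k > 0 cell k).
#' @param annulusGapPx,annulusWidthPx annulus geometry in pixels.
#' @param overlapPairs optional two-column matrix of overlapping label
#'   pairs known from ROI construction.
#' @return a \linkS4class{RoiSet}.
#' @export
roiSet <- function(labels, annulusGapPx = 1, annulusWidthPx = 3,
                   overlapPairs = NULL) {
    storage.mode(labels) <- "integer"
    if (is.null(overlapPairs))
        overlapPairs <- matrix(integer(0), ncol = 2L,
                               dimnames = list(NULL, c("a", "b")))
    new("RoiSet", labels = labels, annulusGapPx = annulusGapPx,
        annulusWidthPx = annulusWidthPx,
        overlapPairs = as.matrix(overlapPairs))
}

#' @rdname RoiSet-class
#' @export
setMethod("labelImage", "RoiSet", function(x) x@labels)

#' @rdname RoiSet-class
#' @export
setMethod("nCells", "RoiSet", function(x) max(x@labels))

#' @rdname RoiSet-class
#' @export
setMethod("overlapPairs", "RoiSet", function(x) x@overlapPairs)

setMethod("show", "RoiSet", function(object) {
    cat("RoiSet:", max(object@labels), "ROIs on a",
        paste(dim(object@labels), collapse = "x"),
        "label image; annulus gap", object@annulusGapPx, "px, width",
        object@annulusWidthPx, "px\n")
    if (nrow(object@overlapPairs))
        cat("recorded overlapping pairs:", nrow(object@overlapPairs), "\n")
    invisible(NULL)
})
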