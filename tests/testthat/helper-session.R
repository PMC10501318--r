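# Shared fixtures and independent brute-force oracles.

# planted class -> category the classifier should assign
expectedCategory <- c(
    INTERNAL_ONLY = "INTERNAL",
    EXTERNAL_GENTLE = "EXTERNAL_GENTLE",
    EXTERNAL_NOXIOUS_ONLY = "EXTERNAL_NOXIOUS",
    BOTH = "EXCLUDED_BOTH",
    SILENT = "NONRESPONDER",
    SPONTANEOUS = "EXCLUDED_SPONTANEOUS",
    PERSISTENT = "EXCLUDED_PERSISTENT")

smallCounts <- c(INTERNAL_ONLY = 2, EXTERNAL_GENTLE = 2,
                 EXTERNAL_NOXIOUS_ONLY = 1, BOTH = 1, SILENT = 1,
                 SPONTANEOUS = 1, PERSISTENT = 1)

# simulate + analyse one session on a small field
makeSession <- function(seed, imageShape = c(64, 64), counts = smallCounts,
                        noiseSd = 0, backgroundLevel = 100,
                        backgroundDriftAmplitude = 10, threshold = 5,
                        plantOverlap = FALSE) {
    sched <- generateSchedule()
    cells <- generateCells(counts, imageShape = imageShape,
                           plantOverlap = plantOverlap, seed = seed)
    movie <- renderMovie(cells, sched, backgroundLevel = backgroundLevel,
                         backgroundDriftAmplitude = backgroundDriftAmplitude,
                         noiseSd = noiseSd, seed = seed + 1000L)
    rois <- roiSetFromCells(cells)
    dff <- computeDff(annulusCorrect(movie, rois), sched)
    responders <- callResponders(dff, sched, threshold)
    flags <- flagExclusions(dff, responders, rois, sched)
    classification <- classifyCells(responders, flags, sched)
    list(schedule = sched, cells = cells, movie = movie, rois = rois,
         dff = dff, responders = responders, flags = flags,
         classification = classification)
}

# build a DFF-stage TraceMatrix directly from a values matrix
dffMatrix <- function(values, boundaries = 1L, rate = 5) {
    drgCalcium:::.traceMatrix(values, "DFF", rate, boundaries)
}

# brute-force per-pixel mean-over-footprint trace extraction
bruteExtract <- function(movie, rois) {
    lab <- labelImage(rois)
    d <- dim(movieData(movie))
    n <- max(lab)
    out <- matrix(0, n, d[3])
    for (k in seq_len(n)) {
        px <- which(lab == k, arr.ind = TRUE)
        for (t in seq_len(d[3])) {
            s <- 0
            for (j in seq_len(nrow(px)))
                s <- s + movieData(movie)[px[j, 1], px[j, 2], t]
            out[k, t] <- s / nrow(px)
        }
    }
    out
}

# brute-force annulus correction using the package's annulus geometry but
# an independent per-pixel accumulation
bruteAnnulusCorrect <- function(movie, rois) {
    raw <- bruteExtract(movie, rois)
    ann <- annulusIndices(rois)
    d <- dim(movieData(movie))
    m <- movieData(movie)
    for (k in seq_along(ann)) {
        H <- d[1]
        for (t in seq_len(d[3])) {
            s <- 0
            for (idx in ann[[k]]) {
                r <- ((idx - 1) %% H) + 1
                c0 <- ((idx - 1) %/% H) + 1
                s <- s + m[r, c0, t]
            }
            raw[k, t] <- raw[k, t] - s / length(ann[[k]])
        }
    }
    raw
}

# brute-force two-pass population SD per pixel over the given frames
bruteSdMap <- function(movie, frames) {
    d <- dim(movieData(movie))
    out <- matrix(0, d[1], d[2])
    for (r in seq_len(d[1])) for (c0 in seq_len(d[2])) {
        x <- movieData(movie)[r, c0, frames]
        mu <- sum(x) / length(x)
        out[r, c0] <- sqrt(sum((x - mu)^2) / length(x))
    }
    out
}

# textbook Pearson chi-square: sum (O - E)^2 / E over the table
bruteChi2 <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}
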