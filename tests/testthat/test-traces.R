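# tiny schedule used for hand-built movies: 7 episodes x 20 frames, 10-frame
# baseline (2 s at 5 Hz)
tinySchedule <- function() generateSchedule(episodeS = 4, baselineS = 2)

test_that("trace extraction reads out footprint means", {
    lab <- matrix(0L, 6, 6)
    lab[2:3, 2:3] <- 1L
    lab[5, 5] <- 2L
    rois <- roiSet(lab)
    arr <- array(7, dim = c(6, 6, 10))
    mov <- movieStack(arr, 5)
    tr <- traceValues(extractTraces(mov, rois))
    expect_true(all(tr == 7))

    # single-pixel ROI returns that pixel's time series
    arr[5, 5, ] <- sin(1:10)
    mov <- movieStack(arr - min(arr), 5)
    tr <- traceValues(extractTraces(mov, rois))
    expect_equal(tr[2, ], sin(1:10) - min(arr))

    # two disjoint ROIs on a two-valued image give two constant traces
    arr2 <- array(1, dim = c(6, 6, 4))
    arr2[5, 5, ] <- 3
    tr2 <- traceValues(extractTraces(movieStack(arr2, 5), rois))
    expect_true(all(tr2[1, ] == 1) && all(tr2[2, ] == 3))
})

test_that("extraction errors name empty and missing labels", {
    lab <- matrix(0L, 6, 6)
    lab[2, 2] <- 2L   # label 1 absent
    mov <- movieStack(array(1, dim = c(6, 6, 3)), 5)
    expect_error(extractTraces(mov, roiSet(lab)), "label\\(s\\): 1")
    expect_error(extractTraces(mov, roiSet(matrix(0L, 6, 6))), "no ROIs")
    expect_error(extractTraces(movieStack(array(1, c(4, 4, 3)), 5),
                               roiSet(lab)), "does not match")
})

test_that("extraction and annulus correction match a brute-force pixel loop", {
    set.seed(42)
    for (rep in 1:3) {
        arr <- array(runif(8 * 8 * 20, 0, 10), dim = c(8, 8, 20))
        lab <- matrix(0L, 8, 8)
        lab[2:3, 2:3] <- 1L
        lab[6:7, 6] <- 2L
        rois <- roiSet(lab, annulusGapPx = 0, annulusWidthPx = 2)
        mov <- movieStack(arr, 5)
        expect_equal(traceValues(extractTraces(mov, rois)),
                     bruteExtract(mov, rois), tolerance = 1e-9,
                     ignore_attr = TRUE)
        expect_equal(traceValues(annulusCorrect(mov, rois)),
                     bruteAnnulusCorrect(mov, rois), tolerance = 1e-9,
                     ignore_attr = TRUE)
    }
})

test_that("a spatially uniform background cancels exactly in annulus correction", {
    sched <- tinySchedule()
    for (seed in 1:5) {
        cells <- generateCells(c(INTERNAL_ONLY = 2, EXTERNAL_GENTLE = 1),
                               imageShape = c(40, 40), seed = seed)
        rois <- roiSetFromCells(cells)
        withBg <- renderMovie(cells, sched, backgroundLevel = 80,
                              backgroundDriftAmplitude = 30, noiseSd = 0)
        noBg <- renderMovie(cells, sched, backgroundLevel = 0,
                            backgroundDriftAmplitude = 0, noiseSd = 0)
        cellOnly <- traceValues(extractTraces(noBg, rois))
        corrected <- traceValues(annulusCorrect(withBg, rois))
        expect_lt(max(abs(corrected - cellOnly)), 1e-9)
    }
})

test_that("correction is the identity on zero background and self-cancels a constant field", {
    sched <- tinySchedule()
    cells <- generateCells(c(INTERNAL_ONLY = 1), imageShape = c(32, 32),
                           seed = 2)
    rois <- roiSetFromCells(cells)
    noBg <- renderMovie(cells, sched, backgroundLevel = 0,
                        backgroundDriftAmplitude = 0, noiseSd = 0)
    expect_equal(traceValues(annulusCorrect(noBg, rois)),
                 traceValues(extractTraces(noBg, rois)),
                 tolerance = 1e-12, ignore_attr = TRUE)

    flat <- movieStack(array(5, dim = c(32, 32, 8)), 5)
    expect_lt(max(abs(traceValues(annulusCorrect(flat, rois)))), 1e-12)
})

test_that("a crowded field yields an annulus error with a remediation hint", {
    lab <- matrix(1L, 5, 5)   # every pixel labeled: no annulus pixels left
    expect_error(annulusIndices(roiSet(lab)), "widen")
})

test_that("percent dF/F arithmetic, flagging and invariances", {
    sched <- tinySchedule()
    n <- sessionFrames(sched)

    const <- drgCalcium:::.traceMatrix(matrix(100, 1, n), "CORRECTED", 5,
                                       episodes(sched)$startFrame)
    expect_true(all(traceValues(computeDff(const, sched)) == 0))

    v <- matrix(100, 2, n)
    v[1, 15] <- 120   # baseline mean 100, one frame at 120 -> 20 %
    tm <- drgCalcium:::.traceMatrix(v, "CORRECTED", 5,
                                    episodes(sched)$startFrame)
    expect_equal(unname(traceValues(computeDff(tm, sched))[1, 15]), 20)

    # scale invariance: scaling a corrected trace leaves dF/F unchanged
    tm3 <- drgCalcium:::.traceMatrix(v * 3.7, "CORRECTED", 5,
                                     episodes(sched)$startFrame)
    expect_equal(traceValues(computeDff(tm3, sched)),
                 traceValues(computeDff(tm, sched)), tolerance = 1e-12)

    # baseline centering: mean dF/F over each baseline window is ~0
    dff <- computeDff(tm, sched)
    for (e in seq_len(nEpisodes(sched))) {
        b <- drgCalcium:::.baselineFrameRange(sched, e)
        expect_lt(abs(mean(traceValues(dff)[2, b])), 1e-9)
    }

    # F0 <= 0 flags the cell-episode as unusable, never silently zeroes
    v[2, 1:10] <- -1
    bad <- drgCalcium:::.traceMatrix(v, "CORRECTED", 5,
                                     episodes(sched)$startFrame)
    expect_warning(dffBad <- computeDff(bad, sched), "unusable")
    expect_true(all(is.na(traceValues(dffBad)[2, 1:20])))
    expect_false(anyNA(traceValues(dffBad)[1, ]))
    expect_equal(S4Vectors::metadata(dffBad)$unusable$cellId, 2L)
    expect_error(computeDff(dffBad, sched), "already")
})

test_that("planted amplitude survives the full correction + dF/F pipeline", {
    sched <- generateSchedule()
    cells <- generateCells(c(INTERNAL_ONLY = 1, EXTERNAL_NOXIOUS_ONLY = 1),
                           imageShape = c(48, 48), amplitudePct = 35,
                           seed = 8)
    mov <- renderMovie(cells, sched, backgroundLevel = 120,
                       backgroundDriftAmplitude = 15, noiseSd = 0)
    dff <- computeDff(annulusCorrect(mov, roiSetFromCells(cells)), sched)
    peaks <- apply(traceValues(dff), 1, max)
    expect_equal(unname(peaks), c(35, 35), tolerance = 1e-6)
})

test_that("episode concatenation preserves cells and records boundaries", {
    sched1 <- generateSchedule(episodeS = 40, baselineS = 8,
                               stimuli = stimulusClasses()[1, ])
    cells <- generateCells(c(INTERNAL_ONLY = 2), imageShape = c(32, 32),
                           seed = 3)
    rois <- roiSetFromCells(cells)
    one <- extractTraces(renderMovie(cells, sched1, noiseSd = 0), rois)
    seven <- concatenateEpisodes(rep(list(one), 7))
    expect_equal(ncol(seven), 1400L)
    expect_equal(episodeBoundaries(seven), as.integer(seq(1, 1201, 200)))
    expect_equal(nrow(seven), 2L)

    expect_identical(traceValues(concatenateEpisodes(list(one))),
                     traceValues(one))

    cells3 <- generateCells(c(INTERNAL_ONLY = 3), imageShape = c(32, 32),
                            seed = 4)
    other <- extractTraces(renderMovie(cells3, sched1, noiseSd = 0),
                           roiSetFromCells(cells3))
    expect_error(concatenateEpisodes(list(one, other)), "cell counts")
    corr <- annulusCorrect(renderMovie(cells, sched1, noiseSd = 0), rois)
    expect_error(concatenateEpisodes(list(one, corr)), "stage")
})
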