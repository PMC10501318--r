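test_that("SD maps respond only where fluorescence varies", {
    sched <- generateSchedule(episodeS = 2, baselineS = 0.4)  # 10-frame eps
    flat <- movieStack(array(3, dim = c(8, 8, 70)), 5,
                       episodes(sched)$startFrame)
    expect_true(all(sdImage(sdMap(flat, sched, "EXTERNAL")) == 0))

    arr <- array(3, dim = c(8, 8, 70))
    arr[4, 5, ] <- rep(c(0, 10), 35)
    mov <- movieStack(arr, 5, episodes(sched)$startFrame)
    m <- sdImage(sdMap(mov, sched, "INTERNAL"))
    expect_gt(m[4, 5], 0)
    expect_equal(sum(m > 0), 1L)
})

test_that("SD maps match a brute-force two-pass per-pixel computation", {
    set.seed(7)
    sched <- generateSchedule(episodeS = 2, baselineS = 0.4)
    arr <- array(runif(16 * 16 * 70, 0, 5), dim = c(16, 16, 70))
    mov <- movieStack(arr, 5, episodes(sched)$startFrame)
    for (site in c("EXTERNAL", "INTERNAL")) {
        eps <- which(episodes(sched)$site == site)
        frames <- unlist(lapply(eps, drgCalcium:::.episodeFrameRange,
                                schedule = sched))
        expect_lt(max(abs(sdImage(sdMap(mov, sched, site)) -
                          bruteSdMap(mov, frames))), 1e-9)
    }
})

test_that("SD maps are invariant to frame order within the pooled set", {
    set.seed(8)
    sched <- generateSchedule(episodeS = 2, baselineS = 0.4)
    arr <- array(runif(8 * 8 * 70), dim = c(8, 8, 70))
    mov <- movieStack(arr, 5, episodes(sched)$startFrame)
    ref <- sdImage(sdMap(mov, sched, "INTERNAL"))
    eps <- which(episodes(sched)$site == "INTERNAL")
    frames <- unlist(lapply(eps, drgCalcium:::.episodeFrameRange,
                            schedule = sched))
    arr2 <- arr
    arr2[, , frames] <- arr[, , sample(frames)]
    expect_equal(sdImage(sdMap(movieStack(arr2, 5, episodes(sched)$startFrame),
                               sched, "INTERNAL")), ref, tolerance = 1e-12)
})

test_that("planted responders light up their footprints in the SD map", {
    ses <- makeSession(41, noiseSd = 0, backgroundDriftAmplitude = 2)
    info <- cellInfo(ses$cells)
    internalCells <- which(info$class == "INTERNAL_ONLY")
    m <- sdImage(sdMap(ses$movie, ses$schedule, "INTERNAL"))
    inFp <- unlist(footprints(ses$cells)[internalCells])
    outFp <- setdiff(seq_along(m), unlist(footprints(ses$cells)))
    expect_gt(mean(m[inFp]), mean(m[outFp]))
})

test_that("requesting a site with no episodes errors", {
    onlyExternal <- generateSchedule(stimuli = stimulusClasses()[1:3, ])
    mov <- movieStack(array(1, dim = c(4, 4, 600)), 5,
                      episodes(onlyExternal)$startFrame)
    expect_error(sdMap(mov, onlyExternal, "INTERNAL"), "no INTERNAL episodes")
    expect_error(sdMap(mov, onlyExternal, "EXTERNAL", episodesUsed = 9),
                 "episodesUsed")
})

test_that("heatmap layout orders blocks, peaks and ties deterministically", {
    sched <- generateSchedule()
    v <- matrix(0, 6, sessionFrames(sched))
    v[1, 1250] <- 30   # internal, peak 30
    v[2, 1250] <- 10   # internal, peak 10
    v[3, 50] <- 15     # gentle
    v[4, 450] <- 15    # noxious
    v[5, 1250] <- 30   # internal, tie with cell 1
    v[6, 60] <- 40     # excluded (overlap): must be omitted
    dff <- dffMatrix(v, episodes(sched)$startFrame)
    cl <- data.frame(cellId = 1:6,
                     category = factor(c("INTERNAL", "INTERNAL",
                                         "EXTERNAL_GENTLE",
                                         "EXTERNAL_NOXIOUS", "INTERNAL",
                                         "EXCLUDED_OVERLAP"),
                                       levels = drgCalcium:::.CATEGORIES))
    lay <- sortHeatmap(dff, cl)
    expect_equal(lay$cellId, c(1, 5, 2, 3, 4))  # tie 30/30 -> lower id first
    expect_equal(as.character(lay$category),
                 c("INTERNAL", "INTERNAL", "INTERNAL", "EXTERNAL_GENTLE",
                   "EXTERNAL_NOXIOUS"))
    expect_equal(attr(lay, "episodeBoundaries"),
                 as.integer(seq(1, 1201, 200)))
    # permutation property: each included cell appears exactly once
    expect_equal(sort(lay$cellId),
                 sort(cl$cellId[cl$category %in%
                                c("INTERNAL", "EXTERNAL_GENTLE",
                                  "EXTERNAL_NOXIOUS")]))
})

test_that("heatmap and SD-map renderings write files", {
    ses <- makeSession(42, imageShape = c(48, 48), noiseSd = 1)
    lay <- sortHeatmap(ses$dff, ses$classification)
    png <- tempfile(fileext = ".png")
    grDevices::png(png, width = 300, height = 200)
    out <- plotResponseHeatmap(ses$dff, lay)
    grDevices::dev.off()
    expect_true(file.exists(png) && file.size(png) > 0)
    expect_identical(out, lay)

    mapPng <- tempfile(fileext = ".png")
    plotSdMap(sdMap(ses$movie, ses$schedule, "INTERNAL"), mapPng)
    expect_true(file.exists(mapPng) && file.size(mapPng) > 0)
})
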