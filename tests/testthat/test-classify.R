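# hand-built dF/F sessions for contract-level checks: default protocol,
# 7 x 200 frames. peakAt() plants one supra-threshold excursion per episode.
sched7 <- generateSchedule()

# values matrix with given per-episode peaks for one cell
dffWithPeaks <- function(peaks, nCells = 1) {
    v <- matrix(0, nCells, sessionFrames(sched7))
    ep <- episodes(sched7)
    for (e in seq_along(peaks)) {
        if (is.na(peaks[e])) next
        at <- ep$startFrame[e] + ep$onsetFrame[e] + 4L
        v[, at] <- peaks[e]
    }
    dffMatrix(v, ep$startFrame)
}

noFlags <- function(n) data.frame(cellId = seq_len(n),
                                  spontaneous = FALSE, persistent = FALSE,
                                  overlap = FALSE)

test_that("responder calls use a strict threshold over the response window", {
    # one cell per case: 20 %, 4.9 %, exactly 5 %
    v <- matrix(0, 3, sessionFrames(sched7))
    v[1, 50] <- 20; v[2, 50] <- 4.9; v[3, 50] <- 5.0
    dff <- dffMatrix(v, episodes(sched7)$startFrame)
    calls <- responderCalls(callResponders(dff, sched7, 5))
    ep1 <- calls[calls$episode == 1, ]
    expect_equal(ep1$isResponder, c(TRUE, FALSE, FALSE))
    expect_equal(ep1$peakDff, c(20, 4.9, 5))

    # supra-threshold activity confined to the baseline is not a response
    v2 <- matrix(0, 1, sessionFrames(sched7))
    v2[1, 10] <- 50
    calls2 <- responderCalls(callResponders(dffMatrix(v2, episodes(sched7)$startFrame),
                                            sched7, 5))
    expect_false(any(calls2$isResponder))
})

test_that("responder calling rejects mismatched inputs and stages", {
    raw <- drgCalcium:::.traceMatrix(matrix(1, 1, 1400), "RAW", 5,
                                     episodes(sched7)$startFrame)
    expect_error(callResponders(raw, sched7), "DFF")
    short <- dffMatrix(matrix(0, 1, 1399), 1L)
    expect_error(callResponders(short, sched7), "frame count")
    expect_error(callResponders(dffWithPeaks(c(10)), sched7, 0),
                 "thresholdPct")
})

test_that("exclusion rules match their definitions", {
    ep <- episodes(sched7)
    # spontaneous: supra-threshold through frames 1..40 of episode 1
    v <- matrix(0, 3, sessionFrames(sched7))
    v[1, 1:40] <- 10
    # persistent: responds in episode 4 then >= threshold for all later frames
    e4onset <- ep$startFrame[4] + ep$onsetFrame[4] - 1L
    v[2, e4onset:ncol(v)] <- 12
    dff <- dffMatrix(v, ep$startFrame)
    rt <- callResponders(dff, sched7, 5)
    rois <- roiSet({m <- matrix(0L, 8, 8); m[1, 1] <- 1L; m[3, 3] <- 2L
                    m[5, 5] <- 3L; m},
                   overlapPairs = cbind(3L, 2L))
    fl <- flagExclusions(dff, rt, rois, sched7)
    expect_true(fl$spontaneous[1])
    expect_false(fl$spontaneous[2])   # elevation follows its first response
    expect_true(fl$persistent[2])
    expect_false(fl$persistent[1])
    expect_equal(fl$overlap, c(FALSE, TRUE, TRUE))

    cl <- classifyCells(rt, fl, sched7)
    expect_equal(as.character(cl$category),
                 c("EXCLUDED_SPONTANEOUS", "EXCLUDED_OVERLAP",
                   "EXCLUDED_OVERLAP"))
})

test_that("category assignment follows the legend definitions", {
    cases <- list(
        list(peaks = c(NA, NA, NA, NA, NA, NA, 20), want = "INTERNAL"),
        list(peaks = c(20, NA, 20, NA, NA, NA, NA), want = "EXTERNAL_GENTLE"),
        list(peaks = c(NA, NA, 20, NA, NA, NA, NA), want = "EXTERNAL_NOXIOUS"),
        list(peaks = c(20, NA, NA, 20, NA, NA, NA), want = "EXCLUDED_BOTH"),
        list(peaks = c(NA, 20, NA, NA, NA, NA, NA), want = "EXTERNAL_GENTLE"),
        list(peaks = rep(NA, 7), want = "NONRESPONDER"))
    for (cs in cases) {
        dff <- dffWithPeaks(cs$peaks)
        rt <- callResponders(dff, sched7, 5)
        cl <- classifyCells(rt, noFlags(1), sched7)
        expect_equal(as.character(cl$category), cs$want)
    }
})

test_that("proportions pool included responders as 100 percent", {
    mk <- function(counts) {
        cats <- rep(c("INTERNAL", "EXTERNAL_NOXIOUS", "EXTERNAL_GENTLE"),
                    counts)
        responderProportions(
            data.frame(cellId = seq_along(cats),
                       category = factor(cats,
                                         levels = drgCalcium:::.CATEGORIES)))
    }
    p <- mk(c(10, 5, 5))
    expect_equal(unname(categoryPercentages(p)), c(50, 25, 25))
    p2 <- mk(c(7, 0, 0))
    expect_equal(unname(categoryPercentages(p2)), c(100, 0, 0))
    expect_equal(sum(categoryPercentages(p)), 100, tolerance = 1e-9)

    allBoth <- data.frame(cellId = 1:3,
                          category = factor(rep("EXCLUDED_BOTH", 3),
                                            levels = drgCalcium:::.CATEGORIES))
    expect_error(responderProportions(allBoth), "empty denominator")
})

test_that("group comparison matches the textbook chi-square", {
    mkSummary <- function(counts, group) {
        new("ProportionSummary",
            counts = stats::setNames(as.integer(counts),
                                     drgCalcium:::.INCLUDED_CATEGORIES),
            group = group)
    }
    a <- mkSummary(c(10, 10, 10), "A")
    same <- compareGroups(a, mkSummary(c(10, 10, 10), "B"))
    expect_equal(same$chi2, 0, tolerance = 1e-12)
    expect_equal(same$p, 1, tolerance = 1e-12)
    expect_equal(same$dof, 2)

    out <- compareGroups(mkSummary(c(20, 5, 25), "A"),
                         mkSummary(c(2, 18, 10), "B"))
    tab <- rbind(c(20, 5, 25), c(2, 18, 10))
    expect_equal(out$chi2, bruteChi2(tab), tolerance = 1e-9)
    expect_equal(out$dof, 2)

    # exhaustive small tables: implementation vs brute force
    set.seed(1)
    for (i in 1:50) {
        tab <- matrix(sample(0:30, 6, replace = TRUE), 2)
        tab[, colSums(tab) == 0] <- 1    # keep all categories populated
        out <- compareGroups(mkSummary(tab[1, ], "A"), mkSummary(tab[2, ], "B"))
        expect_equal(out$chi2, bruteChi2(tab), tolerance = 1e-9)
    }

    # a category empty in both groups is dropped, reducing dof
    expect_warning(red <- compareGroups(mkSummary(c(10, 0, 5), "A"),
                                        mkSummary(c(3, 0, 12), "B")),
                   "dropped")
    expect_equal(red$dof, 1)
})

test_that("categories partition the ROI set and are monotone in threshold", {
    ses <- makeSession(31, noiseSd = 1, plantOverlap = TRUE)
    cl <- ses$classification
    expect_equal(nrow(cl), nrow(cellInfo(ses$cells)))
    expect_equal(sum(table(cl$category)), nCells(ses$rois))

    # noise-free session: responder counts and the included-responder total
    # are both non-increasing as the threshold rises
    ses0 <- makeSession(31, noiseSd = 0, plantOverlap = TRUE)
    nIncluded <- function(thr) {
        rt <- callResponders(ses0$dff, ses0$schedule, thr)
        fl <- flagExclusions(ses0$dff, rt, ses0$rois, ses0$schedule)
        cl <- classifyCells(rt, fl, ses0$schedule)
        c(resp = sum(responderCalls(rt)$isResponder, na.rm = TRUE),
          incl = sum(cl$category %in% c("INTERNAL", "EXTERNAL_GENTLE",
                                        "EXTERNAL_NOXIOUS")))
    }
    counts <- vapply(1:20, nIncluded, numeric(2))
    expect_true(all(diff(counts["resp", ]) <= 0))
    # the included total is only guaranteed monotone below the planted
    # amplitude; at exactly 20 % float round-off decides which of a BOTH
    # cell's episodes drops out first
    expect_true(all(diff(counts["incl", 1:19]) <= 0))

    # with sensor noise the raw responder count stays monotone
    nResp <- vapply(1:20, function(thr)
        sum(responderCalls(callResponders(ses$dff, ses$schedule,
                                          thr))$isResponder, na.rm = TRUE),
        numeric(1))
    expect_true(all(diff(nResp) <= 0))
})

test_that("blinded re-analysis of shuffled, de-identified traces gives identical proportions", {
    ses <- makeSession(17, noiseSd = 1)
    # de-identify: permute rows and relabel cells 1..n, as a blinded analyst
    # would receive them
    set.seed(99)
    perm <- sample(nrow(ses$dff))
    v <- traceValues(ses$dff)[perm, ]
    f0 <- S4Vectors::metadata(ses$dff)$baselineF0[perm, ]
    blindDff <- drgCalcium:::.traceMatrix(v, "DFF", 5,
                                          episodeBoundaries(ses$dff),
                                          extraMeta = list(baselineF0 = f0))
    rt <- callResponders(blindDff, ses$schedule, 5)
    # no overlap record travels with de-identified traces
    blank <- roiSet({m <- labelImage(ses$rois); m})
    fl <- flagExclusions(blindDff, rt, blank, ses$schedule)
    cl <- classifyCells(rt, fl, ses$schedule)
    expect_equal(categoryCounts(responderProportions(cl)),
                 categoryCounts(responderProportions(ses$classification)))
})
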