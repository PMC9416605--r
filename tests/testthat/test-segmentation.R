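test_that("channel split converts codes to centered volts and recombines", {
  set.seed(8)
  codes <- matrix(sample(0:4095, 8 * 30, TRUE), 8, 30)
  rec <- EMGSession(codes, arm = "both")
  tr <- splitChannels(rec)
  expect_identical(dim(tr), c(8L, 30L))
  expect_equal(unname(tr), adcToVoltage(codes))
  ## round-trip recombination
  expect_identical(apply(tr, 2, voltageToAdc), codes)
  ## single-arm record -> 4 traces
  rec4 <- EMGSession(codes[1:4, ], arm = "right")
  expect_identical(nrow(splitChannels(rec4)), 4L)
})

test_that("cycle peaks land on the ground-truth extension maxima", {
  s <- smallCohort()$sessions$S01_left
  gt <- s@metadata$groundTruth
  tr <- splitChannels(s)
  pk <- detectCyclePeaks(tr[1, ])
  expect_length(pk, 3L)
  expect_false(is.unsorted(pk))
  truth <- gt$peakSensor1[gt$movement == "M2"]
  expect_true(all(abs(pk - truth) <= 250))
  bursts <- attr(pk, "bursts")
  expect_identical(dim(bursts), c(3L, 2L))
  expect_true(all(pk >= bursts[, 1] & pk <= bursts[, 2]))

  ## flat trace fails with a diagnostic
  expect_error(detectCyclePeaks(rep(0, 60000)), "flat")
  ## a single-cycle session yields one peak
  s1 <- synthSession(1, "left",
                     cohortSpec(nSubjects = 1, armsPerSubject = 1,
                                timing = protocolTiming(cycles = 1),
                                seed = 5L))
  expect_length(detectCyclePeaks(splitChannels(s1)[1, ], nCycles = 1), 1L)
  ## asking for more cycles than exist is an error
  expect_error(detectCyclePeaks(splitChannels(s1)[1, ], nCycles = 3),
               "qualifying")
})

test_that("cycle windows recover the slot geometry", {
  ## arithmetic oracle: anchors spaced 86,000 apart, record ending at the
  ## last cycle end; last-anchor-to-end spans (5 - f) slots exactly
  f <- 0.56
  slot <- 14000
  anchors <- (1 + f) * slot + c(0, 86000, 172000)
  L <- 172000 + 6 * slot
  pk <- structure(as.integer(round(anchors)),
                  bursts = cbind(round(anchors) - 100L,
                                 round(anchors) + 100L))
  cyc <- deriveCycles(pk, L, anchorFrac = f)
  expect_equal(cyc$slotLength, slot, tolerance = 1e-6)
  expect_equal(cyc$cycleLength, 86000)
  expect_identical(nrow(cyc$windows), 3L)
  expect_equal(cyc$windows[1, 1], 1, tolerance = 2)

  ## single peak fallback: record ending 4.5 slots after a mid-slot-2 peak
  pk1 <- 21000L
  cyc1 <- deriveCycles(pk1, 21000 + 4.5 * 14000, anchorFrac = 0.5)
  expect_equal(cyc1$slotLength, 14000, tolerance = 1e-6)
  expect_identical(nrow(cyc1$windows), 1L)

  ## every derived window covers all six ground-truth ranges of its cycle
  s <- smallCohort()$sessions$S02_left
  gt <- s@metadata$groundTruth
  tr <- splitChannels(s)
  cycS <- deriveCycles(detectCyclePeaks(tr[1, ]), ncol(tr))
  for (ci in 1:3) {
    gtc <- gt[gt$cycle == ci, ]
    w <- cycS$windows[ci, ]
    ## window covers >= 90% of every true slot of its cycle
    cover <- (pmin(w[2], gtc$slotEnd) - pmax(w[1], gtc$slotStart) + 1) /
      (gtc$slotEnd - gtc$slotStart + 1)
    expect_true(all(cover >= 0.9))
  }
  expect_error(deriveCycles(integer(0), 1000), "at least one")
})

test_that("six-way split is contiguous, aligned and near-equal", {
  sl <- splitCycleIntoMovements(c(1, 84000))
  expect_identical(dim(sl), c(6L, 2L))
  expect_true(all(sl[, 2] - sl[, 1] + 1L == 14000L))
  expect_identical(unname(sl[1, 1]), 1L)
  expect_identical(unname(sl[6, 2]), 84000L)
  ## contiguity
  expect_identical(unname(sl[-1, 1]), unname(sl[-6, 2] + 1L))
  ## remainder goes to the last slots, lengths differ by at most 1
  sl2 <- splitCycleIntoMovements(c(1, 83999))
  len <- unname(sl2[, 2] - sl2[, 1] + 1L)
  expect_identical(sum(len), 83999L)
  expect_lte(diff(range(len)), 1)
  expect_identical(len, c(13999L, 14000L, 14000L, 14000L, 14000L, 14000L))
  expect_error(splitCycleIntoMovements(c(1, 4)), "shorter")
})

test_that("homogenization trims symmetrically with the floor/ceil tie-break", {
  x <- seq_len(14000)
  h <- homogenize(x)
  expect_length(h, 13000L)
  expect_identical(h[1], 501L)
  expect_identical(h[13000], 13500L)
  ## d = 0: unchanged
  expect_identical(homogenize(seq_len(13000)), seq_len(13000))
  ## odd difference: extra sample dropped from the back
  h1 <- homogenize(seq_len(13001))
  expect_identical(h1[1], 1L)
  expect_identical(h1[13000], 13000L)
  ## matrices are trimmed column-wise, rows stay aligned
  m <- rbind(1:14000, (1:14000) * 2L, (1:14000) * 3L, (1:14000) * 4L)
  hm <- homogenize(m)
  expect_identical(dim(hm), c(4L, 13000L))
  expect_identical(hm[2, 1], 2L * 501L)
  ## short input: error unless padding enabled
  expect_error(homogenize(1:500), "pad = FALSE")
  expect_length(homogenize(1:12999, pad = TRUE), 13000L)
})

test_that("session segmentation yields labeled 4 x 13000 segments", {
  s <- smallCohort()$sessions$S01_left
  segs <- segmentSession(s)
  expect_length(segs, 18L)
  for (sg in segs) {
    expect_identical(dim(segmentSamples(sg)), c(4L, 13000L))
    expect_identical(subjectId(sg), "S01")
    expect_identical(arm(sg), "left")
  }
  expect_identical(vapply(segs, movement, ""),
                   s@metadata$groundTruth$movement)

  ## the same source range is applied to all sensors: segment rows equal
  ## the corresponding session samples
  tr <- splitChannels(s)
  sg <- segs[[8]]
  rng <- sg@sourceRange[1]:sg@sourceRange[2]
  expect_equal(unname(segmentSamples(sg)), unname(tr[, rng]))
})

test_that("segment files and manifest round-trip the labels", {
  d <- withr::local_tempdir()
  segs <- smallSegments()[1:6]
  manifest <- writeSegments(segs, d)
  expect_identical(nrow(manifest), 6L)
  expect_true(all(file.exists(file.path(d, manifest$file))))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- readSegment(file.path(d, manifest$file[3]))
  expect_identical(movement(back), movement(segs[[3]]))
  expect_identical(dim(segmentSamples(back)), c(4L, 13000L))
  expect_equal(segmentSamples(back), segmentSamples(segs[[3]]),
               tolerance = 1e-5)
})

test_that("label recovery against generator truth holds across seeds", {
  ok <- 0L; total <- 0L
  for (seed in 101:105) {
    s <- synthSession(1, "left",
                      cohortSpec(nSubjects = 1, armsPerSubject = 1,
                                 seed = seed))
    segs <- segmentSession(s)
    lab <- vapply(segs, movement, "")
    ok <- ok + sum(lab == s@metadata$groundTruth$movement)
    total <- total + length(lab)
  }
  expect_gte(ok / total, 0.95)
})
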