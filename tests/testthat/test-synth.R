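test_that("movement bursts follow the protocol envelope and calibration", {
  pr <- movementProfiles()
  timing <- protocolTiming()
  ## extension: sensor-1 calibration spans about -1..0.8 V peak-to-peak
  b <- synthMovementBurst(pr[2, ], timing, seed = 5)
  expect_identical(dim(b), c(4L, 14000L))
  pp <- max(b[1, ]) - min(b[1, ])
  expect_gte(pp, 1.5)
  expect_lte(pp, 2.0)
  ## realized hold peak equals the profile amplitude; all values in range
  hold <- attr(b, "holdRange")
  expect_equal(max(abs(b[1, hold[1]:hold[2]])), pr$s1[2])
  expect_true(all(abs(b) <= 1.5))
  ## near-zero during the 4 s display phase
  expect_lt(max(abs(b[1, 1:4000])), 0.05)

  ## all-zero amplitude -> flat zero traces
  pr0 <- pr[1, ]
  pr0[c("s1", "s2", "s3", "s4")] <- 0
  expect_true(all(synthMovementBurst(pr0, timing, seed = 1) == 0))

  ## determinism
  expect_identical(synthMovementBurst(pr[3, ], timing, seed = 42),
                   synthMovementBurst(pr[3, ], timing, seed = 42))

  ## amplitude beyond the sensor range is rejected
  prBad <- pr[1, ]
  prBad$s2 <- 1.6
  expect_error(synthMovementBurst(prBad, timing, seed = 1), "1.5 V")
})

test_that("burst plateaus concentrate their energy in the profile band", {
  pr <- movementProfiles()
  for (m in c(1L, 4L, 6L)) {
    b <- synthMovementBurst(pr[m, ], protocolTiming(), seed = 300 + m)
    hold <- attr(b, "holdRange")
    for (s in c(1L, 3L)) {
      x <- b[s, hold[1]:hold[2]]
      pg <- stats::spec.pgram(x, taper = 0, detrend = FALSE, plot = FALSE)
      f <- pg$freq * 1000
      inband <- f >= pr$centerHz[m] - pr$bandHz[m] / 2 &
        f <= pr$centerHz[m] + pr$bandHz[m] / 2
      expect_gte(sum(pg$spec[inband]) / sum(pg$spec), 0.8)
    }
  }
})

test_that("sessions have protocol structure and self-consistent ground truth", {
  sp <- cohortSpec(nSubjects = 1, armsPerSubject = 1, seed = 99L)
  s <- synthSession(1, "left", sp)
  expect_s4_class(s, "EMGSession")
  ## length = cycles * 6 slots + inter-cycle gaps
  expect_identical(ncol(channels(s)), 3L * 6L * 14000L + 2L * 2000L)
  gt <- s@metadata$groundTruth
  expect_identical(nrow(gt), 18L)
  expect_identical(gt$movement, rep(names(movementClasses()), 3))

  ## single-cycle session: exactly 6 movement windows
  sp1 <- cohortSpec(nSubjects = 1, armsPerSubject = 1,
                    timing = protocolTiming(cycles = 1), seed = 99L)
  expect_identical(nrow(synthSession(1, "left", sp1)@metadata$groundTruth),
                   6L)

  ## ground-truth boundaries are consistent with the generating envelope:
  ## the deterministic slot envelope leaves its baseline exactly at the
  ## recorded active start, and the realized signal energy brackets it
  tr <- splitChannels(s)
  env <- semgflex:::slotEnvelope(0.9, sp$timing, 1000, sp$baselineAmp)
  expect_identical(env$activeStart, 4001L)
  for (i in which(gt$movement == "M2")) {
    expect_identical(gt$activeStart[i], gt$slotStart[i] + 4000L)
    expect_identical(gt$activeEnd[i], gt$slotStart[i] - 1L + 10500L)
    displayRms <- sqrt(mean(tr[1, gt$slotStart[i]:(gt$activeStart[i] - 1)]^2))
    activeRms <- sqrt(mean(tr[1, gt$activeStart[i]:gt$activeEnd[i]]^2))
    expect_gt(activeRms, 5 * displayRms)
    ## stochastic onset estimate (3x display level, 100 ms smoothing)
    slot <- gt$slotStart[i]:gt$slotEnd[i]
    e <- semgflex:::movingRms(tr[1, slot], 101)
    onset <- gt$slotStart[i] - 1L +
      which(e > 3 * stats::median(e[1:4000]))[1]
    expect_lt(abs(onset - gt$activeStart[i]), 200)
  }

  ## sensor 1 peaks during extension in every cycle
  for (ci in 1:3) {
    gtc <- gt[gt$cycle == ci, ]
    peaks <- vapply(seq_len(6), function(m)
      max(abs(tr[1, gtc$slotStart[m]:gtc$slotEnd[m]])), 0)
    expect_identical(which.max(peaks), 2L)
  }
})

test_that("cohorts are balanced, sized to spec and bit-deterministic", {
  co <- smallCohort()
  expect_length(co$sessions, 2L)
  expect_identical(nrow(co$truth), 36L)
  expect_true(all(table(co$truth$movement) == 6L))

  ## identical spec -> bit-identical channels
  co2 <- synthCohort(cohortSpec(nSubjects = 2, armsPerSubject = 1,
                                seed = 2024L))
  expect_identical(lapply(co2$sessions, channels),
                   lapply(co$sessions, channels))

  ## default spec arithmetic: 15 x 2 x 3 x 6 = 540, 90 per class
  sp <- cohortSpec()
  expect_identical(sp$nSubjects * sp$armsPerSubject * sp$timing$cycles * 6L,
                   540L)

  ## single subject, single arm: 18 instances
  co1 <- synthCohort(cohortSpec(nSubjects = 1, armsPerSubject = 1,
                                seed = 1L))
  expect_identical(nrow(co1$truth), 18L)
})

test_that("cohort files round-trip through the session dialect", {
  d <- withr::local_tempdir()
  co <- smallCohort()
  paths <- writeCohort(co, d)
  expect_true(file.exists(file.path(d, "labels.csv")))
  back <- readSessionCsv(file.path(d, "S01_left.csv"))
  expect_identical(channels(back), channels(co$sessions$S01_left))
  labs <- read.csv(file.path(d, "labels.csv"))
  expect_identical(nrow(labs), 36L)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(protocolTiming(display_s = 0), "positive")
  expect_error(protocolTiming(movement_total_s = 8), "too short")
  pr <- movementProfiles()
  pr$centerHz[1] <- 480
  expect_error(cohortSpec(profiles = pr), "500")
  pr <- movementProfiles()
  pr$s1[1] <- 2
  expect_error(cohortSpec(profiles = pr), "1.5")
})
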