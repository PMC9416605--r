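## Synthetic sEMG cohort generator. Each movement instance is band-limited
## Gaussian noise shaped by a trapezoidal amplitude envelope that follows
## the acquisition protocol (4 s cue, 3 s preparation ramp, 3 s hold), with
## per-movement spectral bands and per-sensor amplitudes calibrated to the
## printed dominant-movement ranges. Not a physiological motor-unit model:
## it reproduces the amplitude/timing/spectral structure the pipeline
## exploits, nothing more.

#' Acquisition protocol timing
#'
#' Timing of one movement slot and the cycle structure: a 4 s on-screen
#' cue, 3 s to prepare and execute, 3 s holding the position. The slot
#' total (default 14 s) exceeds the 10 s active protocol so a recorded
#' movement spans more than the 13,000 samples the homogenization step
#' trims to; cycles are separated by a short rest gap.
#'
#' @param display_s cue duration (s).
#' @param prepare_s preparation/execution ramp duration (s).
#' @param hold_s hold duration (s).
#' @param movement_total_s total recorded slot per movement (s); must
#'   leave at least 0.5 s after the hold for the release ramp.
#' @param intercycle_gap_s rest gap between cycles (s).
#' @param cycles repetitions of the six-movement sequence.
#' @return A `ProtocolTiming` list.
#' @examples
#' protocolTiming()
#' @export
protocolTiming <- function(display_s = 4, prepare_s = 3, hold_s = 3,
                           movement_total_s = 14, intercycle_gap_s = 2,
                           cycles = 3) {
  t <- list(display_s = display_s, prepare_s = prepare_s, hold_s = hold_s,
            movement_total_s = movement_total_s,
            intercycle_gap_s = intercycle_gap_s, cycles = as.integer(cycles))
  if (any(unlist(t[1:5]) <= 0) || t$cycles < 1L)
    stopf("all protocol durations must be positive and cycles >= 1")
  if (movement_total_s < display_s + prepare_s + hold_s + 0.5)
    stopf("movement_total_s too short for display + prepare + hold + release")
  class(t) <- c("ProtocolTiming", "list")
  t
}

#' Default per-movement signal profiles
#'
#' Peak plateau amplitude (V, centered) of each movement on each sensor,
#' plus a movement-specific spectral band. Amplitudes honor the
#' calibration of the reference recordings: sensor 1 peaks during
#' extension (about -1..0.8 V), sensor 2 during radial deviation
#' (-0.18..0.12 V), sensor 3 during power grip (-0.20..0.22 V) and
#' sensor 4 during ulnar deviation (-0.53..0.53 V); amplitudes here are
#' half the peak-to-peak span. Bands are distinct per movement (inside
#' the 20-450 Hz sEMG range) so the six classes are spectrally
#' separable, which is the working assumption of the FFT features.
#'
#' @return A data.frame with columns `movement`, `s1`-`s4` (peak volts)
#'   and `centerHz`, `bandHz` (passband center and width).
#' @examples
#' movementProfiles()
#' @export
movementProfiles <- function() {
  data.frame(
    movement = names(movementClasses()),
    s1 = c(0.06, 0.90, 0.10, 0.07, 0.08, 0.05),
    s2 = c(0.12, 0.10, 0.08, 0.15, 0.09, 0.07),
    s3 = c(0.10, 0.08, 0.09, 0.07, 0.21, 0.15),
    s4 = c(0.08, 0.12, 0.53, 0.10, 0.11, 0.09),
    centerHz = c(70, 120, 170, 220, 280, 340),
    bandHz = c(60, 60, 60, 60, 60, 60),
    stringsAsFactors = FALSE)
}

#' Cohort specification for the synthetic generator
#'
#' Default values reproduce the study conditions: 15 subjects, both
#' forearms, 3 cycles of 6 movements = 540 movement instances (90 per
#' class).
#'
#' @param nSubjects number of subjects.
#' @param armsPerSubject 1 or 2 forearms.
#' @param timing a [protocolTiming()] list.
#' @param profiles a [movementProfiles()] data.frame.
#' @param seed master seed; every burst draws from a substream derived
#'   from it and the (subject, arm, cycle, movement) indices, so any
#'   single burst is reproducible in isolation.
#' @param baselineAmp resting-noise peak amplitude (V) during cue
#'   phases and inter-cycle gaps.
#' @param ampJitter per-(subject, arm) multiplicative amplitude jitter
#'   (fractional half-range, default 0.10).
#' @param centerJitterHz per-(subject, arm) spectral-center jitter
#'   half-range in Hz.
#' @return A `CohortSpec` list.
#' @examples
#' sp <- cohortSpec(nSubjects = 1, armsPerSubject = 1)
#' @export
cohortSpec <- function(nSubjects = 15, armsPerSubject = 2,
                       timing = protocolTiming(),
                       profiles = movementProfiles(), seed = 104729L,
                       baselineAmp = 0.02, ampJitter = 0.10,
                       centerJitterHz = 10) {
  stopifnot(isCount(nSubjects), armsPerSubject %in% 1:2,
            inherits(timing, "ProtocolTiming"))
  if (!all(c("movement", "s1", "s2", "s3", "s4", "centerHz", "bandHz") %in%
             names(profiles)) || nrow(profiles) != 6L)
    stopf("profiles must be a 6-row movementProfiles() data.frame")
  amps <- as.matrix(profiles[, c("s1", "s2", "s3", "s4")])
  if (any(amps < 0) || any(amps > ADC_REFERENCE_V))
    stopf("profile amplitudes must lie in [0, 1.5] V")
  lo <- profiles$centerHz - profiles$bandHz / 2
  hi <- profiles$centerHz + profiles$bandHz / 2
  if (any(lo <= 0) || any(hi >= 500))
    stopf("spectral bands must lie inside (0, 500) Hz")
  spec <- list(nSubjects = as.integer(nSubjects),
               armsPerSubject = as.integer(armsPerSubject),
               timing = timing, profiles = profiles,
               seed = as.integer(seed), baselineAmp = baselineAmp,
               ampJitter = ampJitter, centerJitterHz = centerJitterHz)
  class(spec) <- c("CohortSpec", "list")
  spec
}

## Band-limited unit-variance Gaussian noise (zero-phase Butterworth).
bandNoise <- function(n, centerHz, bandHz, fs, order = 4) {
  lo <- max(centerHz - bandHz / 2, 1) / (fs / 2)
  hi <- min(centerHz + bandHz / 2, fs / 2 - 1) / (fs / 2)
  bf <- signal::butter(order, c(lo, hi), type = "pass")
  as.numeric(signal::filtfilt(bf, rnorm(n)))
}

## Amplitude envelope (volts) of one movement slot. Trapezoid with a
## mildly domed hold plateau (quadratic droop toward the plateau edges)
## so the realized activity maximum concentrates near the plateau centre.
slotEnvelope <- function(amp, timing, fs, baselineAmp, droop = 0.3) {
  d <- as.integer(round(timing$display_s * fs))
  p <- as.integer(round(timing$prepare_s * fs))
  h <- as.integer(round(timing$hold_s * fs))
  n <- as.integer(round(timing$movement_total_s * fs))
  r <- as.integer(round(0.5 * fs))
  floorV <- min(baselineAmp, amp)
  edge <- amp * (1 - droop)
  delta <- (seq_len(h) - (h + 1) / 2) / (h / 2)
  env <- c(rep(floorV, d),
           seq(floorV, edge, length.out = p),
           amp * (1 - droop * delta^2),
           seq(edge, floorV, length.out = r),
           rep(floorV, n - d - p - h - r))
  list(env = env, activeStart = d + 1L, activeEnd = d + p + h + r,
       holdStart = d + p + 1L, holdEnd = d + p + h, n = n)
}

#' Synthesize one movement burst (4 sensors)
#'
#' Band-limited Gaussian noise shaped by the slot envelope: near-baseline
#' during the cue, a linear ramp through preparation, a (mildly domed)
#' plateau during the hold, then release back to baseline. The noise is
#' rescaled so the realized peak over the hold equals the profile's
#' per-sensor amplitude exactly; sensors with zero amplitude yield silent
#' traces. Values are clipped to the +-1.5 V sensor range.
#'
#' @param profile one row of [movementProfiles()].
#' @param timing a [protocolTiming()] list.
#' @param seed integer seed for this burst.
#' @param samplingRate Hz (default 1000).
#' @param baselineAmp baseline peak amplitude (V).
#' @return 4 x n voltage matrix with attributes `activeRange` and
#'   `holdRange` (1-based inclusive sample ranges of the active phase and
#'   the hold plateau).
#' @examples
#' b <- synthMovementBurst(movementProfiles()[2, ], protocolTiming(), seed = 1)
#' dim(b)
#' @export
synthMovementBurst <- function(profile, timing, seed,
                               samplingRate = 1000, baselineAmp = 0.02) {
  fs <- samplingRate
  amps <- as.numeric(profile[c("s1", "s2", "s3", "s4")])
  if (any(amps > ADC_REFERENCE_V))
    stopf("profile amplitude exceeds the 1.5 V sensor range")
  out <- NULL
  withSeed(seed, {
    for (s in 1:4) {
      e <- slotEnvelope(amps[s], timing, fs, baselineAmp)
      if (is.null(out)) out <- matrix(0, 4L, e$n)
      if (amps[s] <= 0 && baselineAmp <= 0) next
      noise <- bandNoise(e$n, profile$centerHz, profile$bandHz, fs)
      if (amps[s] <= 0) {
        out[s, ] <- 0
        next
      }
      hold <- e$holdStart:e$holdEnd
      g <- max(abs(noise[hold]) * e$env[hold] / amps[s])
      if (g > 0) out[s, ] <- pmin(pmax(noise * e$env / g,
                                       -ADC_REFERENCE_V), ADC_REFERENCE_V)
    }
    e <- slotEnvelope(max(amps), timing, fs, baselineAmp)
    attr(out, "activeRange") <- c(e$activeStart, e$activeEnd)
    attr(out, "holdRange") <- c(e$holdStart, e$holdEnd)
  })
  out
}

## Apply the per-(subject, arm) jitter to the profile table.
jitterProfiles <- function(spec, subject, armIdx) {
  pr <- spec$profiles
  withSeed(deriveSeed(spec$seed, subject, armIdx, 0L, 0L), {
    fac <- 1 + runif(6, -spec$ampJitter, spec$ampJitter)
    pr[, c("s1", "s2", "s3", "s4")] <-
      pr[, c("s1", "s2", "s3", "s4")] * fac
    pr$centerHz <- pr$centerHz +
      runif(6, -spec$centerJitterHz, spec$centerJitterHz)
  })
  pr
}

#' Synthesize one single-arm session
#'
#' Concatenates `cycles` cycles, each the six movements in protocol order
#' M1..M6, separated by inter-cycle gaps of baseline noise, then encodes
#' the voltages as 12-bit ADC codes. The per-instance ground truth (slot
#' range, active range, realized sensor-1 peak position) is stored in
#' `metadata(session)$groundTruth`.
#'
#' @param subject subject index (1-based).
#' @param arm `"left"` or `"right"`.
#' @param spec a [cohortSpec()].
#' @return An [EMGSession-class] with 4 channels.
#' @examples
#' s <- synthSession(1, "left", cohortSpec(nSubjects = 1, armsPerSubject = 1,
#'   timing = protocolTiming(cycles = 1)))
#' @export
synthSession <- function(subject, arm = c("left", "right"),
                         spec = cohortSpec()) {
  arm <- match.arg(arm)
  armIdx <- match(arm, c("left", "right"))
  fs <- 1000
  timing <- spec$timing
  pr <- jitterProfiles(spec, subject, armIdx)
  slotN <- as.integer(round(timing$movement_total_s * fs))
  gapN <- as.integer(round(timing$intercycle_gap_s * fs))
  nCyc <- timing$cycles
  total <- nCyc * 6L * slotN + (nCyc - 1L) * gapN
  volts <- matrix(0, 4L, total)
  truth <- vector("list", nCyc * 6L)
  pos <- 0L
  for (cyc in seq_len(nCyc)) {
    if (cyc > 1L) {
      withSeed(deriveSeed(spec$seed, subject, armIdx, cyc, 99L), {
        for (s in 1:4) {
          g <- bandNoise(gapN, 235, 430, fs)
          volts[s, pos + seq_len(gapN)] <-
            g / max(abs(g)) * spec$baselineAmp
        }
      })
      pos <- pos + gapN
    }
    for (m in seq_len(6L)) {
      b <- synthMovementBurst(pr[m, ],
                              timing,
                              deriveSeed(spec$seed, subject, armIdx, cyc, m),
                              samplingRate = fs,
                              baselineAmp = spec$baselineAmp)
      volts[, pos + seq_len(slotN)] <- b
      act <- attr(b, "activeRange")
      pk <- act[1L] - 1L + which.max(abs(b[1L, act[1L]:act[2L]]))
      truth[[(cyc - 1L) * 6L + m]] <- data.frame(
        subjectId = sprintf("S%02d", subject), arm = arm, cycle = cyc,
        movement = names(movementClasses())[m],
        slotStart = pos + 1L, slotEnd = pos + slotN,
        activeStart = pos + act[1L], activeEnd = pos + act[2L],
        peakSensor1 = pos + pk, stringsAsFactors = FALSE)
      pos <- pos + slotN
    }
  }
  EMGSession(voltageToAdc(volts) |> matrix(4L, total),
             samplingRate = fs, subjectId = sprintf("S%02d", subject),
             arm = arm,
             metadata = list(groundTruth = do.call(rbind, truth),
                             seed = spec$seed))
}

#' Synthesize a full cohort
#'
#' One session per (subject, arm); at defaults, 15 subjects x 2 arms x
#' 3 cycles x 6 movements = 540 labeled movement instances (90/class).
#'
#' @param spec a [cohortSpec()].
#' @return A list with elements `sessions` (list of [EMGSession-class])
#'   and `truth` (combined ground-truth data.frame).
#' @examples
#' co <- synthCohort(cohortSpec(nSubjects = 1, armsPerSubject = 1,
#'   timing = protocolTiming(cycles = 1)))
#' nrow(co$truth)
#' @export
synthCohort <- function(spec = cohortSpec()) {
  arms <- c("left", "right")[seq_len(spec$armsPerSubject)]
  sessions <- list()
  for (i in seq_len(spec$nSubjects)) {
    for (a in arms) {
      sessions[[sprintf("S%02d_%s", i, a)]] <- synthSession(i, a, spec)
    }
  }
  truth <- do.call(rbind, lapply(sessions,
                                 function(s) s@metadata$groundTruth))
  rownames(truth) <- NULL
  list(sessions = sessions, truth = truth)
}

#' Write a cohort to disk
#'
#' One session CSV per (subject, arm) in the session-file dialect, plus a
#' single `labels.csv` ground-truth sidecar (movement, cycle and sample
#' ranges per instance, 1-based inclusive).
#'
#' @param cohort result of [synthCohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(cohort$sessions)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    writeSessionCsv(cohort$sessions[[nm]], p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, "labels.csv")
  utils::write.csv(cohort$truth, side, row.names = FALSE)
  invisible(c(paths, side))
}
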