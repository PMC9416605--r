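## Five-stage division algorithm: load the joint vector, split it into
## per-sensor traces, locate the per-cycle extension bursts on sensor 1
## (the reference sensor: extension produces its largest amplitudes),
## derive the cycle windows, split each cycle into six equal movement
## slots, and homogenize every slot to exactly 13,000 samples.

#' Split a session into per-sensor voltage traces
#'
#' Converts the raw ADC codes to centered volts and returns one trace per
#' channel, in sensor order (left band 1-4, then right band 1-4 for
#' two-band sessions).
#'
#' @param record an [EMGSession-class].
#' @return A numeric matrix, channels x samples, in volts.
#' @examples
#' s <- EMGSession(matrix(2048L, 4, 10))
#' dim(splitChannels(s))
#' @export
splitChannels <- function(record) {
  stopifnot(is(record, "EMGSession"))
  validObject(record)
  v <- adcToVoltage(record@channels)
  matrix(v, nrow(record@channels), ncol(record@channels),
         dimnames = list(paste0("ch", seq_len(nrow(record@channels))), NULL))
}

#' Detect per-cycle reference peaks on sensor 1
#'
#' Finds the `nCycles` extension bursts on the reference trace: the
#' signal is rectified and smoothed with a moving-RMS envelope
#' (`smoothMs`), contiguous regions above `threshold` times the global
#' envelope maximum are merged into bursts (gaps shorter than 0.5 s are
#' bridged), the `nCycles` strongest bursts at least
#' `minSepFrac * length/nCycles` samples apart are kept, and within each
#' burst the peak is the maximum of the rectified raw signal.
#'
#' @param trace1 numeric voltage trace of sensor 1.
#' @param nCycles expected number of cycles (default 3).
#' @param samplingRate Hz.
#' @param smoothMs moving-RMS window (ms).
#' @param threshold activity threshold as a fraction of the global
#'   envelope maximum.
#' @param minSepFrac minimum peak separation as a fraction of the
#'   expected cycle length (`length(trace1)/nCycles`).
#' @return Sorted integer peak positions (1-based), with attribute
#'   `bursts`: an nCycles x 2 matrix of burst start/end samples.
#' @export
detectCyclePeaks <- function(trace1, nCycles = 3, samplingRate = 1000,
                             smoothMs = 200, threshold = 0.5,
                             minSepFrac = 0.6) {
  n <- length(trace1)
  if (n < nCycles * 10L)
    stopf("trace too short (%d samples) for %d cycles", n, nCycles)
  env <- movingRms(trace1, round(smoothMs / 1000 * samplingRate))
  emax <- max(env)
  if (emax <= 0)
    stopf("segmentation failed: flat trace, no activity detected")
  above <- env >= threshold * emax
  if (!any(above))
    stopf("segmentation failed: no activity above threshold")
  ## contiguous runs above threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  ## bridge sub-0.5 s gaps between runs
  if (nrow(runs) > 1L) {
    keep <- list(runs[1L, ])
    for (i in 2L:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[i, 1L] - last[2L] < 0.5 * samplingRate) {
        keep[[length(keep)]][2L] <- runs[i, 2L]
      } else keep[[length(keep) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
  }
  peakEnv <- apply(runs, 1L, function(w) max(env[w[1L]:w[2L]]))
  ord <- order(peakEnv, decreasing = TRUE)
  minSep <- minSepFrac * n / nCycles
  sel <- integer(0)
  for (i in ord) {
    mid <- mean(runs[i, ])
    if (all(abs(mid - vapply(sel, function(j) mean(runs[j, ]), 0)) >= minSep))
      sel <- c(sel, i)
    if (length(sel) == nCycles) break
  }
  if (length(sel) < nCycles)
    stopf(paste("segmentation failed: found %d qualifying activity",
                "bursts, expected %d"), length(sel), nCycles)
  sel <- sel[order(runs[sel, 1L])]
  peaks <- vapply(sel, function(i) {
    w <- runs[i, 1L]:runs[i, 2L]
    w[which.max(abs(trace1[w]))]
  }, 0L)
  structure(as.integer(peaks), bursts = runs[sel, , drop = FALSE])
}

#' Derive cycle windows from reference peaks
#'
#' Estimates the movement-slot length and positions one window of six
#' slots per cycle, anchored on the reference burst of each cycle.
#' Extension is the second movement of the protocol order, and under the
#' protocol timing its sustained activity is centered at fraction
#' `anchorFrac` of its slot, so each window starts
#' `(1 + anchorFrac) * slot` before its anchor.
#'
#' The slot length comes from the span between the last anchor and the
#' end of the record, which covers exactly `6 - 1 - anchorFrac` slots
#' when the record ends with the last cycle and - unlike the inter-anchor
#' spacing - contains no inter-cycle rest gap. When at least two anchors
#' exist, the estimate is cross-checked against the median inter-anchor
#' period and replaced by `period/6` if inconsistent (e.g. trailing data
#' after the last cycle).
#'
#' @param peaks integer peak positions from [detectCyclePeaks()] (its
#'   `bursts` attribute, when present, provides more stable anchors).
#' @param traceLength total samples in the trace.
#' @param nMovements movements per cycle (default 6).
#' @param anchorFrac assumed position of the anchor within its slot
#'   (fraction, default 0.56 = midpoint of the 5.5-10.25 s sustained
#'   activity of a 14 s slot).
#' @return A `CycleWindows` list: `peaks`, `windows` (cycles x 2 matrix
#'   of start/end samples, 1-based inclusive, clipped to the record),
#'   `slotLength`, `cycleLength`.
#' @export
deriveCycles <- function(peaks, traceLength, nMovements = 6,
                         anchorFrac = 0.56) {
  if (length(peaks) < 1L) stopf("need at least one reference peak")
  bursts <- attr(peaks, "bursts")
  anchors <- if (!is.null(bursts)) rowMeans(bursts) else as.numeric(peaks)
  anchors <- sort(anchors)
  slotFromEnd <- (traceLength - anchors[length(anchors)]) /
    (nMovements - 1 - anchorFrac)
  if (length(anchors) >= 2L) {
    period <- median(diff(anchors))
    slot <- slotFromEnd
    if (slotFromEnd < 0.7 * period / nMovements ||
        slotFromEnd > 1.05 * period / nMovements)
      slot <- period / nMovements
  } else {
    period <- nMovements * slotFromEnd
    slot <- slotFromEnd
  }
  if (slot < 1) stopf("estimated slot length < 1 sample")
  windows <- t(vapply(anchors, function(a) {
    s <- max(1, round(a - (1 + anchorFrac) * slot))
    e <- min(traceLength, s + round(nMovements * slot) - 1)
    c(s, e)
  }, c(0, 0)))
  if (nrow(windows) > 1L &&
      any(windows[-1L, 1L] <= windows[-nrow(windows), 2L] - slot / 2))
    stopf("estimated cycle windows overlap; segmentation failed")
  structure(list(peaks = as.integer(peaks), windows = windows,
                 slotLength = slot,
                 cycleLength = if (length(anchors) >= 2L) period
                               else nMovements * slot),
            class = c("CycleWindows", "list"))
}

#' Split one cycle window into six movement slots
#'
#' Divides the window into `nMovements` contiguous near-equal slots in
#' protocol order; when the window length is not divisible, the extra
#' samples go to the last slots (lengths differ by at most one). The same
#' sample ranges apply to all sensors of the arm.
#'
#' @param window length-2 start/end (1-based inclusive).
#' @param nMovements slots per cycle.
#' @return nMovements x 2 integer matrix of slot ranges.
#' @export
splitCycleIntoMovements <- function(window, nMovements = 6) {
  len <- window[2L] - window[1L] + 1L
  if (len < nMovements) stopf("cycle window shorter than %d samples", nMovements)
  base <- len %/% nMovements
  rem <- len %% nMovements
  sizes <- rep(base, nMovements)
  if (rem > 0L)
    sizes[(nMovements - rem + 1L):nMovements] <- base + 1L
  ends <- window[1L] - 1L + cumsum(sizes)
  starts <- ends - sizes + 1L
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Homogenize a movement vector to a fixed length
#'
#' Symmetric trim: with `d = length(x) - target`, drops `floor(d/2)`
#' samples from the front and `ceiling(d/2)` from the back. Inputs
#' shorter than the target are an error unless `pad = TRUE`, in which
#' case zeros are added with the same front/back convention.
#'
#' @param x numeric vector (or 4-row matrix, trimmed column-wise).
#' @param target output length (default 13,000).
#' @param pad allow zero-padding of short inputs.
#' @return Vector (or matrix) of exactly `target` samples.
#' @examples
#' length(homogenize(rnorm(14000)))  # drops 500 front, 500 back
#' @export
homogenize <- function(x, target = SEGMENT_LENGTH, pad = FALSE) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  d <- n - target
  if (d < 0) {
    if (!pad)
      stopf("input (%d samples) shorter than target %d and pad = FALSE",
            n, target)
    front <- floor(-d / 2); back <- ceiling(-d / 2)
    if (is.matrix(x))
      return(cbind(matrix(0, nrow(x), front), x, matrix(0, nrow(x), back)))
    return(c(rep(0, front), x, rep(0, back)))
  }
  keep <- (floor(d / 2) + 1L):(n - ceiling(d / 2))
  if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
}

## Segment the 4 traces of one arm. Internal: shared by segmentSession.
segmentArm <- function(traces, subjectId, armLabel, nCycles,
                       movementOrder, samplingRate, anchorFrac,
                       target = SEGMENT_LENGTH) {
  peaks <- detectCyclePeaks(traces[1L, ], nCycles = nCycles,
                            samplingRate = samplingRate)
  cyc <- deriveCycles(peaks, ncol(traces), nMovements = length(movementOrder),
                      anchorFrac = anchorFrac)
  segs <- list()
  for (ci in seq_len(nrow(cyc$windows))) {
    slots <- splitCycleIntoMovements(cyc$windows[ci, ],
                                     nMovements = length(movementOrder))
    for (m in seq_len(nrow(slots))) {
      rng <- slots[m, 1L]:slots[m, 2L]
      seg <- homogenize(traces[, rng, drop = FALSE], target = target,
                        pad = TRUE)
      off <- floor((length(rng) - target) / 2)
      src <- if (length(rng) >= target)
        c(slots[m, 1L] + off, slots[m, 1L] + off + target - 1L)
      else c(slots[m, 1L], slots[m, 2L])
      segs[[length(segs) + 1L]] <- MovementSegment(
        seg, movement = movementOrder[m], cycle = ci,
        subjectId = subjectId, arm = armLabel, sourceRange = src)
    }
  }
  segs
}

#' Segment a session into labeled movement instances
#'
#' Runs the full division pipeline on a session: channel split and
#' voltage conversion, reference-peak detection on sensor 1 of each arm,
#' cycle-window derivation, six-way slot split and homogenization to
#' 13,000 samples. A single-arm session yields `cycles * 6` segments
#' (18 at protocol defaults); a two-band session yields twice that.
#'
#' @param record an [EMGSession-class].
#' @param nCycles cycles expected in the session.
#' @param movementOrder movement labels in protocol order.
#' @param anchorFrac see [deriveCycles()].
#' @return List of [MovementSegment-class] objects.
#' @seealso [writeSegments()] to store them with a manifest.
#' @export
segmentSession <- function(record, nCycles = 3,
                           movementOrder = names(movementClasses()),
                           anchorFrac = 0.56) {
  traces <- splitChannels(record)
  armSets <- if (nrow(traces) == 8L) {
    list(left = traces[1:4, ], right = traces[5:8, ])
  } else {
    stats::setNames(list(traces), record@arm)
  }
  segs <- list()
  for (a in names(armSets)) {
    segs <- c(segs, tryCatch(
      segmentArm(armSets[[a]], record@subjectId, a, nCycles,
                 movementOrder, record@samplingRate, anchorFrac),
      error = function(e)
        stopf("segmentation of subject %s arm %s failed: %s",
              record@subjectId, a, conditionMessage(e))))
  }
  segs
}

#' Write movement segments with a manifest
#'
#' One CSV per segment (a metadata header line, then 4 semicolon-
#' separated rows of 13,000 voltages), filenames encoding
#' subject/arm/cycle/movement, plus a `manifest.csv` listing every file.
#'
#' @param segments list of [MovementSegment-class].
#' @param dir output directory.
#' @param digits significant digits for the stored voltages.
#' @return Invisibly, the manifest data.frame.
#' @export
writeSegments <- function(segments, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(segments, function(sg) {
    fn <- sprintf("%s_%s_c%d_%s.csv", sg@subjectId, sg@arm, sg@cycle,
                  sg@movement)
    con <- file(file.path(dir, fn), "w")
    writeLines(sprintf("# subject=%s arm=%s cycle=%d movement=%s rate=1000",
                       sg@subjectId, sg@arm, sg@cycle, sg@movement), con)
    for (s in 1:4)
      writeLines(paste0(signif(sg@samples[s, ], digits), collapse = ";"), con)
    close(con)
    data.frame(file = fn, subjectId = sg@subjectId, arm = sg@arm,
               cycle = sg@cycle, movement = sg@movement,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read one segment CSV written by [writeSegments()]
#'
#' @param path segment file path.
#' @return A [MovementSegment-class].
#' @export
readSegment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[1L]
  kv <- regmatches(header, gregexpr("[a-zA-Z]+=[^[:space:]]+", header))[[1L]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  rows <- lines[-1L][nzchar(lines[-1L])]
  if (length(rows) != 4L) stopf("segment file must have 4 sensor rows")
  samples <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(r, ";", fixed = TRUE)[[1L]])))
  MovementSegment(samples, movement = meta[["movement"]],
                  cycle = as.integer(meta[["cycle"]]),
                  subjectId = meta[["subject"]], arm = meta[["arm"]])
}
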