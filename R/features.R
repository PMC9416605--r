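## FFT-magnitude features. Two representations per movement instance:
## (a) the full half spectrum, 6,500 magnitudes per sensor (26,000 after
## concatenating the 4 sensors), with the 5 lowest positions zeroed as
## DC-region exclusion; (b) the average-of-sequences vector, one mean
## magnitude per ~10 Hz band, 50 values per sensor (200 concatenated).

HALF_SPECTRUM <- 6500L
DC_EXCLUDE <- 5L

## |DFT| of one 13,000-sample sensor trace.
sensorFftMag <- function(x) {
  if (length(x) != SEGMENT_LENGTH)
    stopf("expected %d samples per sensor, got %d (no implicit resampling)",
          SEGMENT_LENGTH, length(x))
  Mod(fft(x))
}

#' Full half-spectrum features of one segment
#'
#' Per sensor, the magnitudes of the first half of the 13,000-point
#' discrete Fourier transform (positions 1-6,500, a bin resolution of
#' 1000/13000 ~ 0.077 Hz), with the first five positions set to zero
#' (DC-region exclusion); the four sensors are concatenated in order,
#' giving 26,000 values per movement instance.
#'
#' @param segment a [MovementSegment-class] or a 4 x 13000 numeric matrix
#'   of voltages.
#' @return Numeric vector of length 26,000.
#' @examples
#' seg <- matrix(rnorm(4 * 13000, sd = 0.1), 4)
#' length(fullFftFeatures(seg))
#' @export
fullFftFeatures <- function(segment) {
  m <- if (is(segment, "MovementSegment")) segment@samples else segment
  if (!is.matrix(m) || nrow(m) != 4L)
    stopf("segment must have 4 sensor rows")
  out <- vapply(1:4, function(s) {
    h <- sensorFftMag(m[s, ])[seq_len(HALF_SPECTRUM)]
    h[seq_len(DC_EXCLUDE)] <- 0
    h
  }, numeric(HALF_SPECTRUM))
  as.numeric(out)
}

#' Average-of-sequences FFT features of one sensor
#'
#' The 50-value banded representation: with `vectorFFT = |fft(x)|`
#' (1-based), bin i is the mean of positions `5 + 130*(i-1)` through
#' `130*i` - 126 magnitudes per bin, the first five positions (DC region)
#' never contributing, and the four positions between consecutive bins
#' skipped exactly as the band pointers advance. Bin 50 ends at position
#' 6,500, so each bin summarizes one ~10 Hz band of the half spectrum.
#' `cleanBins = TRUE` instead averages contiguous 130-value bins
#' (positions `130*(i-1)+1` to `130*i`, DC region zeroed), for users who
#' consider the inter-bin gap an artifact; the default is the literal
#' banding above.
#'
#' @param x numeric vector of exactly 13,000 samples (one sensor), or a
#'   4 x 13000 matrix, in which case the per-sensor vectors are
#'   concatenated (200 values).
#' @param cleanBins use contiguous 130-value bins instead of the literal
#'   126-value bands.
#' @return Numeric vector of 50 values (or 200 for a 4-sensor matrix).
#' @examples
#' length(fftAvgSequences(rnorm(13000)))
#' @export
fftAvgSequences <- function(x, cleanBins = FALSE) {
  if (is.matrix(x)) {
    if (nrow(x) != 4L) stopf("segment matrix must have 4 sensor rows")
    return(as.numeric(vapply(1:4, function(s)
      fftAvgSequences(x[s, ], cleanBins = cleanBins), numeric(50L))))
  }
  vectorFFT <- sensorFftMag(x)
  out <- numeric(50L)
  if (cleanBins) {
    vectorFFT[seq_len(DC_EXCLUDE)] <- 0
    for (i in 1:50) out[i] <- mean(vectorFFT[(130L * (i - 1L) + 1L):(130L * i)])
  } else {
    startValue <- 5L
    endValue <- 130L
    for (i in 1:50) {
      out[i] <- mean(vectorFFT[startValue:endValue])
      startValue <- startValue + 130L
      endValue <- endValue + 130L
    }
  }
  out
}

#' Assemble the classifier input matrix
#'
#' Computes the chosen feature representation for every segment and
#' stacks them into a [GestureDataset-class]: the assay `"features"` is
#' features x instances (26,000 x n in full mode, 200 x n in average
#' mode), `colData` carries subject, arm, cycle and movement, and rows
#' are ordered deterministically by (subject, arm, cycle, movement).
#'
#' @param segments list of [MovementSegment-class].
#' @param mode `"full"` or `"average"`.
#' @param cleanBins passed to [fftAvgSequences()] in average mode.
#' @return A [GestureDataset-class].
#' @seealso [featureMatrix()], [labelMatrix()]
#' @export
assembleMatrix <- function(segments, mode = c("average", "full"),
                           cleanBins = FALSE) {
  mode <- match.arg(mode)
  if (!length(segments)) stopf("no segments to assemble")
  meta <- do.call(rbind, lapply(segments, function(sg)
    data.frame(subjectId = sg@subjectId, arm = sg@arm, cycle = sg@cycle,
               movement = sg@movement, stringsAsFactors = FALSE)))
  ord <- order(meta$subjectId, meta$arm, meta$cycle, meta$movement)
  segments <- segments[ord]
  meta <- meta[ord, , drop = FALSE]
  feat <- vapply(segments, function(sg) {
    if (mode == "full") fullFftFeatures(sg)
    else fftAvgSequences(sg@samples, cleanBins = cleanBins)
  }, numeric(if (mode == "full") 4L * HALF_SPECTRUM else 200L))
  colnames(feat) <- make.unique(sprintf("%s_%s_c%d_%s", meta$subjectId,
                                        meta$arm, meta$cycle, meta$movement))
  rownames(meta) <- colnames(feat)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    colData = S4Vectors::DataFrame(meta),
    metadata = list(mode = mode, labelLevels = names(movementClasses()),
                    cleanBins = cleanBins))
  new("GestureDataset", se)
}

#' Extract the instances x features matrix of a GestureDataset
#'
#' @param gd a [GestureDataset-class].
#' @return `featureMatrix()`: numeric matrix, instances x features.
#'   `labelMatrix()`: one-hot instances x 6 matrix (each row sums to 1).
#'   `labels()`-style movement vector available via
#'   `colData(gd)$movement`.
#' @export
featureMatrix <- function(gd) {
  stopifnot(is(gd, "GestureDataset"))
  t(SummarizedExperiment::assay(gd, "features"))
}

#' @rdname featureMatrix
#' @export
labelMatrix <- function(gd) {
  stopifnot(is(gd, "GestureDataset"))
  lv <- S4Vectors::metadata(gd)$labelLevels
  mv <- SummarizedExperiment::colData(gd)$movement
  Y <- matrix(0, length(mv), length(lv), dimnames = list(NULL, lv))
  Y[cbind(seq_along(mv), match(mv, lv))] <- 1
  Y
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated instances x features matrix plus a JSON sidecar
#' (`<path>.json`) recording the mode, dimensions, label order and the
#' per-instance metadata.
#'
#' @param gd a [GestureDataset-class].
#' @param path output file path (`.tsv`).
#' @return `writeFeatureMatrix()` returns `path` invisibly;
#'   `readFeatureMatrix()` reconstructs the [GestureDataset-class]
#'   (feature values only round-trip to written precision).
#' @export
writeFeatureMatrix <- function(gd, path) {
  X <- featureMatrix(gd)
  utils::write.table(X, path, sep = "\t", row.names = TRUE,
                     col.names = FALSE, quote = FALSE)
  meta <- as.data.frame(SummarizedExperiment::colData(gd))
  jsonlite::write_json(
    list(mode = S4Vectors::metadata(gd)$mode,
         n_instances = nrow(X), n_features = ncol(X),
         labelLevels = S4Vectors::metadata(gd)$labelLevels,
         instances = meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(path, sep = "\t", row.names = 1L,
                           header = FALSE)
  feat <- t(as.matrix(tab))
  dimnames(feat) <- list(NULL, rownames(tab))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    colData = S4Vectors::DataFrame(side$instances),
    metadata = list(mode = side$mode, labelLevels = side$labelLevels))
  new("GestureDataset", se)
}
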