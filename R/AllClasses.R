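#' Movement classes of the acquisition protocol
#'
#' The six wrist/hand gestures of the test protocol, in protocol order.
#' Each test cycle executes them in this fixed order; the segmentation
#' stage relies on extension (M2) producing the largest sensor-1 burst.
#'
#' @return Named character vector: names `M1`-`M6`, values the gesture names.
#' @examples
#' movementClasses()
#' @export
movementClasses <- function() {
  c(M1 = "flexion", M2 = "extension", M3 = "ulnar deviation",
    M4 = "radial deviation", M5 = "power grip", M6 = "lateral grip")
}

ADC_MAX <- 4095L
ADC_SUPPLY_V <- 3.0
ADC_REFERENCE_V <- 1.5

#' EMGSession: one raw acquisition session
#'
#' Container for the raw integer ADC sample stream of one recording
#' session: 4 channels for a single forearm band or 8 channels for a
#' two-band (left + right) session, sampled at a common rate (1000 Hz in
#' the acquisition protocol). Codes are 12-bit counts in \[0, 4095\].
#'
#' @slot channels integer matrix, one row per sensor channel (sensors 1-4
#'   of the left arm, then 1-4 of the right for two-band sessions),
#'   columns are samples.
#' @slot samplingRate sampling frequency in Hz.
#' @slot subjectId subject identifier.
#' @slot arm `"left"`, `"right"` or `"both"`.
#' @slot metadata free-form list (the synthetic generator stores its
#'   ground-truth table here).
#'
#' @aliases EMGSession
#' @exportClass EMGSession
setClass("EMGSession",
  representation(channels = "matrix", samplingRate = "numeric",
                 subjectId = "character", arm = "character",
                 metadata = "list"),
  prototype(samplingRate = 1000, subjectId = "S00", arm = "left",
            metadata = list()))

setValidity("EMGSession", function(object) {
  ch <- object@channels
  if (!is.numeric(ch)) return("channels must be a numeric/integer matrix")
  if (!nrow(ch) %in% c(4L, 8L))
    return("channels must have 4 (one arm) or 8 (both arms) rows")
  if (anyNA(ch)) return("channels must not contain NA")
  if (any(ch < 0) || any(ch > ADC_MAX))
    return(sprintf("ADC codes must lie in [0, %d]", ADC_MAX))
  if (any(ch != floor(ch))) return("ADC codes must be integers")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (!object@arm %in% c("left", "right", "both"))
    return("arm must be 'left', 'right' or 'both'")
  if (object@arm == "both" && nrow(ch) != 8L)
    return("arm = 'both' requires 8 channels")
  if (object@arm != "both" && nrow(ch) != 4L)
    return("single-arm sessions carry 4 channels")
  TRUE
})

#' Construct an EMGSession
#'
#' @param channels integer matrix of ADC codes, 4 or 8 rows.
#' @param samplingRate sampling frequency in Hz (default 1000).
#' @param subjectId subject identifier.
#' @param arm `"left"`, `"right"` or `"both"`.
#' @param metadata free-form list.
#' @return An [EMGSession-class] object.
#' @examples
#' s <- EMGSession(matrix(0L, 4, 100), subjectId = "S01", arm = "left")
#' dim(channels(s))
#' @export
EMGSession <- function(channels, samplingRate = 1000, subjectId = "S00",
                       arm = c("left", "right", "both"), metadata = list()) {
  arm <- match.arg(arm)
  storage.mode(channels) <- "integer"
  new("EMGSession", channels = channels, samplingRate = samplingRate,
      subjectId = subjectId, arm = arm, metadata = metadata)
}

#' MovementSegment: one homogenized movement instance
#'
#' One labeled movement execution extracted by the segmentation stage:
#' 4 sensors by exactly 13,000 voltage samples (13 s at 1000 Hz), with
#' movement class, cycle index, subject and arm.
#'
#' @slot samples numeric 4 x 13000 matrix of centered voltages (V).
#' @slot movement one of `"M1"`-`"M6"`.
#' @slot cycle cycle index (1-based).
#' @slot subjectId subject identifier.
#' @slot arm `"left"` or `"right"`.
#' @slot sourceRange integer length-2: first and last sample (1-based,
#'   inclusive) of the segment in the source session, or `c(NA, NA)`.
#'
#' @aliases MovementSegment
#' @exportClass MovementSegment
setClass("MovementSegment",
  representation(samples = "matrix", movement = "character",
                 cycle = "integer", subjectId = "character",
                 arm = "character", sourceRange = "integer"))

SEGMENT_LENGTH <- 13000L

setValidity("MovementSegment", function(object) {
  s <- object@samples
  if (nrow(s) != 4L) return("samples must have 4 sensor rows")
  if (ncol(s) != SEGMENT_LENGTH)
    return(sprintf("samples must have exactly %d columns", SEGMENT_LENGTH))
  if (anyNA(s) || !all(is.finite(s))) return("samples must be finite")
  if (!object@movement %in% names(movementClasses()))
    return("movement must be one of M1..M6")
  if (!object@arm %in% c("left", "right"))
    return("arm must be 'left' or 'right'")
  TRUE
})

#' Construct a MovementSegment
#'
#' @param samples numeric 4 x 13000 voltage matrix.
#' @param movement movement class `"M1"`-`"M6"`.
#' @param cycle cycle index.
#' @param subjectId subject identifier.
#' @param arm `"left"` or `"right"`.
#' @param sourceRange optional 1-based inclusive sample range in the
#'   source session.
#' @return A [MovementSegment-class] object.
#' @export
MovementSegment <- function(samples, movement, cycle = 1L, subjectId = "S00",
                            arm = "left", sourceRange = c(NA_integer_, NA_integer_)) {
  dimnames(samples) <- NULL
  new("MovementSegment", samples = samples, movement = movement,
      cycle = as.integer(cycle), subjectId = subjectId, arm = arm,
      sourceRange = as.integer(sourceRange))
}

#' GestureDataset: assembled feature matrix with one-hot labels
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' the assembled classifier input: the assay `"features"` is features x
#' instances (26,000 rows in full mode, 200 in average mode), `colData`
#' carries subject, arm, cycle and movement per instance, and
#' `metadata()` records the feature mode and label order.
#'
#' @aliases GestureDataset
#' @exportClass GestureDataset
setClass("GestureDataset", contains = "SummarizedExperiment")

setValidity("GestureDataset", function(object) {
  md <- S4Vectors::metadata(object)
  if (is.null(md$mode) || !md$mode %in% c("full", "average"))
    return("metadata()$mode must be 'full' or 'average'")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subjectId", "arm", "cycle", "movement")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!all(cd$movement %in% names(movementClasses())))
    return("movement labels must be M1..M6")
  TRUE
})

#' GestureNet: trained two-layer feedforward gesture classifier
#'
#' Weights and preprocessing of the pattern-recognition network: one
#' hidden layer of logistic-sigmoid units and a softmax output layer over
#' the six movement classes, trained on min-max scaled features.
#'
#' @slot W1,b1 hidden-layer weights (features x hidden) and bias.
#' @slot W2,b2 output-layer weights (hidden x classes) and bias.
#' @slot scaleCenter,scaleHalf per-feature affine scaling fitted on the
#'   training partition: scaled = (x - center) / half, mapping the
#'   training range onto \[-1, 1\].
#' @slot classLevels class labels in output order.
#' @slot config the [netConfig()] list used for training.
#' @slot history list: epochs run, loss traces, stop reason, wall time.
#'
#' @aliases GestureNet
#' @exportClass GestureNet
setClass("GestureNet",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", scaleCenter = "numeric",
                 scaleHalf = "numeric", classLevels = "character",
                 config = "list", history = "list"))

#' ConfusionReport: classification evaluation summary
#'
#' Per-partition confusion matrices (rows = true class, columns =
#' predicted) with per-class sensitivity and precision and overall
#' accuracy, for the train/validation/test partitions and their union.
#'
#' @slot confusion named list of square count matrices
#'   (`train`, `validation`, `test`, `overall`).
#' @slot accuracy named numeric, one entry per partition.
#' @slot sensitivity,precision class x partition numeric matrices.
#' @slot epochsRun epochs executed during training.
#'
#' @aliases ConfusionReport
#' @exportClass ConfusionReport
setClass("ConfusionReport",
  representation(confusion = "list", accuracy = "numeric",
                 sensitivity = "matrix", precision = "matrix",
                 epochsRun = "integer"))
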