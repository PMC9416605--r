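#' Accessors for semgflex classes
#'
#' `channels()` returns the raw ADC code matrix of a session;
#' `samplingRate()`, `subjectId()` and `arm()` return the corresponding
#' metadata fields (defined for both [EMGSession-class] and
#' [MovementSegment-class] where meaningful); `segmentSamples()` returns
#' a segment's 4 x 13000 voltage matrix and `movement()` its class label.
#'
#' @param x an `EMGSession` or `MovementSegment`.
#' @return The slot value.
#' @name accessors
#' @aliases channels samplingRate subjectId arm segmentSamples movement
#' @examples
#' s <- EMGSession(matrix(0L, 4, 10), subjectId = "S01")
#' subjectId(s); samplingRate(s)
NULL

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("arm", function(x) standardGeneric("arm"))
#' @rdname accessors
#' @export
setGeneric("segmentSamples", function(x) standardGeneric("segmentSamples"))
#' @rdname accessors
#' @export
setGeneric("movement", function(x) standardGeneric("movement"))

#' @rdname accessors
setMethod("channels", "EMGSession", function(x) x@channels)
#' @rdname accessors
setMethod("samplingRate", "EMGSession", function(x) x@samplingRate)
#' @rdname accessors
setMethod("subjectId", "EMGSession", function(x) x@subjectId)
#' @rdname accessors
setMethod("arm", "EMGSession", function(x) x@arm)

#' @rdname accessors
setMethod("segmentSamples", "MovementSegment", function(x) x@samples)
#' @rdname accessors
setMethod("movement", "MovementSegment", function(x) x@movement)
#' @rdname accessors
setMethod("subjectId", "MovementSegment", function(x) x@subjectId)
#' @rdname accessors
setMethod("arm", "MovementSegment", function(x) x@arm)
#' @rdname accessors
setMethod("samplingRate", "MovementSegment", function(x) 1000)

setMethod("show", "EMGSession", function(object) {
  cat(sprintf("EMGSession: subject %s, arm %s\n", object@subjectId,
              object@arm))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@channels), ncol(object@channels),
              object@samplingRate,
              ncol(object@channels) / object@samplingRate))
  if (!is.null(object@metadata$groundTruth))
    cat(sprintf("  ground truth: %d movement instances\n",
                nrow(object@metadata$groundTruth)))
  invisible(NULL)
})

setMethod("show", "MovementSegment", function(object) {
  cat(sprintf("MovementSegment: %s (%s), cycle %d, subject %s, arm %s\n",
              object@movement, movementClasses()[object@movement],
              object@cycle, object@subjectId, object@arm))
  cat(sprintf("  4 sensors x %d samples, range [%.3f, %.3f] V\n",
              ncol(object@samples), min(object@samples),
              max(object@samples)))
  invisible(NULL)
})

setMethod("show", "GestureNet", function(object) {
  cat(sprintf("GestureNet: %d -> %d sigmoid -> %d softmax\n",
              nrow(object@W1), ncol(object@W1), ncol(object@W2)))
  cat(sprintf("  classes: %s\n", paste(object@classLevels, collapse = " ")))
  cat(sprintf("  trained %d epochs (%s)\n", object@history$epochs,
              object@history$stopReason))
  invisible(NULL)
})

setMethod("show", "ConfusionReport", function(object) {
  cat("ConfusionReport\n")
  for (p in names(object@confusion)) {
    cat(sprintf("  %-10s n = %4d  accuracy = %.3f\n", p,
                sum(object@confusion[[p]]), object@accuracy[[p]]))
  }
  invisible(NULL)
})
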