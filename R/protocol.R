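## Wire protocol: one 17-character datagram per joint sample of one band,
## a start marker followed by four zero-padded 4-digit decimal ADC fields
## (sensors 1-4). Session files store the raw code stream semicolon-
## separated in sample-major order.

#' Encode four ADC codes as a 17-character datagram
#'
#' Frames one joint sample of a four-sensor band: the start marker
#' followed by four zero-padded 4-digit decimal fields, sensor order 1-4.
#' Field width 4 is exact for a 12-bit converter (0-4095), so every frame
#' is fixed-width and parseable by offset.
#'
#' @param codes integer vector of length 4, each in \[0, 4095\].
#' @param marker single start character (default `"A"`).
#' @return A 17-character string.
#' @examples
#' encodeFrame(c(0, 4095, 0, 1234))
#' @seealso [decodeFrame()]
#' @export
encodeFrame <- function(codes, marker = "A") {
  if (length(codes) != 4L) stopf("expected 4 sensor codes, got %d", length(codes))
  if (nchar(marker) != 1L) stopf("start marker must be a single character")
  bad <- which(!is.finite(codes) | codes < 0 | codes > ADC_MAX |
                 codes != floor(codes))
  if (length(bad))
    stopf("ADC code out of range [0, %d] for sensor %d: %s",
          ADC_MAX, bad[1L], format(codes[bad[1L]]))
  paste0(marker, paste0(sprintf("%04d", as.integer(codes)), collapse = ""))
}

#' Decode a 17-character datagram into four ADC codes
#'
#' @param message 17-character frame produced by [encodeFrame()].
#' @param marker expected start character (default `"A"`).
#' @return Integer vector of the 4 ADC codes in sensor order.
#' @examples
#' decodeFrame("A0000409500001234")
#' @export
decodeFrame <- function(message, marker = "A") {
  if (length(message) != 1L || !is.character(message))
    stopf("message must be a single string")
  if (nchar(message) != 17L)
    stopf("frame length must be 17 characters, got %d", nchar(message))
  if (substr(message, 1L, 1L) != marker)
    stopf("bad start marker: expected '%s', got '%s'", marker,
          substr(message, 1L, 1L))
  payload <- substr(message, 2L, 17L)
  if (!grepl("^[0-9]{16}$", payload))
    stopf("frame payload must be 16 decimal digits")
  codes <- as.integer(substring(payload, c(1L, 5L, 9L, 13L),
                                c(4L, 8L, 12L, 16L)))
  if (any(codes > ADC_MAX))
    stopf("decoded ADC code exceeds %d", ADC_MAX)
  codes
}

#' Convert ADC codes to centered voltages (and back)
#'
#' The sensors output 0-3 V around a 1.5 V reference, digitized by a
#' 12-bit converter. `adcToVoltage()` maps code c to
#' `3 * c / 4095 - 1.5` volts (so 0 -> -1.5 V, 4095 -> +1.5 V);
#' `voltageToAdc()` is its rounded inverse, clipped to the code range.
#'
#' @param code integer ADC count(s) in \[0, 4095\].
#' @param volts centered voltage(s) in \[-1.5, 1.5\].
#' @return Numeric voltages, or integer codes.
#' @examples
#' adcToVoltage(c(0, 2048, 4095))
#' voltageToAdc(adcToVoltage(1234L))
#' @export
adcToVoltage <- function(code) {
  if (any(!is.finite(code) | code < 0 | code > ADC_MAX))
    stopf("ADC code out of range [0, %d]", ADC_MAX)
  ADC_SUPPLY_V * code / ADC_MAX - ADC_REFERENCE_V
}

#' @rdname adcToVoltage
#' @export
voltageToAdc <- function(volts) {
  code <- round((volts + ADC_REFERENCE_V) / ADC_SUPPLY_V * ADC_MAX)
  as.integer(pmin(pmax(code, 0), ADC_MAX))
}

#' Write / read a session file
#'
#' Sessions are stored as plain text: an optional `#`-prefixed header
#' line recording subject, arm and sampling rate, then the integer ADC
#' codes semicolon-separated in sample-major order (frame t contributes
#' channel 1..K before frame t+1 starts). The round trip is bit-exact.
#'
#' @param record an [EMGSession-class].
#' @param path file path (conventionally `.csv`).
#' @param framesPerLine frames written per text line (layout only; any
#'   whitespace around tokens is ignored on read).
#' @return `writeSessionCsv()` returns `path` invisibly;
#'   `readSessionCsv()` returns an [EMGSession-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' s <- EMGSession(matrix(0:39, 4, 10), subjectId = "S01")
#' writeSessionCsv(s, f)
#' identical(channels(readSessionCsv(f)), channels(s))
#' @export
writeSessionCsv <- function(record, path, framesPerLine = 250L) {
  stopifnot(is(record, "EMGSession"))
  validObject(record)
  ch <- record@channels
  ## sample-major: column-wise flatten of the channels matrix
  tokens <- format(as.vector(ch), scientific = FALSE, trim = TRUE)
  nchan <- nrow(ch)
  per <- nchan * framesPerLine
  lines <- vapply(split(tokens, ceiling(seq_along(tokens) / per)),
                  paste0, character(1), collapse = ";")
  header <- sprintf("# subject=%s arm=%s rate=%g channels=%d",
                    record@subjectId, record@arm, record@samplingRate, nchan)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' @rdname writeSessionCsv
#' @export
readSessionCsv <- function(path) {
  if (!file.exists(path)) stopf("no such session file: %s", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- list(subject = "S00", arm = "left", rate = 1000, channels = 8L)
  if (length(header)) {
    kv <- regmatches(header[1L],
                     gregexpr("[a-zA-Z]+=[^[:space:]]+", header[1L]))[[1L]]
    for (p in kv) {
      key <- sub("=.*", "", p); val <- sub(".*=", "", p)
      if (key == "subject") meta$subject <- val
      if (key == "arm") meta$arm <- val
      if (key == "rate") meta$rate <- as.numeric(val)
      if (key == "channels") meta$channels <- as.integer(val)
    }
  }
  tokens <- unlist(strsplit(paste(body, collapse = ";"), ";", fixed = TRUE))
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stopf("empty session file: %s", path)
  if (any(!grepl("^[0-9]+$", tokens)))
    stopf("non-integer token in session file: '%s'",
          tokens[which(!grepl("^[0-9]+$", tokens))[1L]])
  nchan <- meta$channels
  if (length(tokens) %% nchan != 0L)
    stopf("token count %d not divisible by %d channels", length(tokens), nchan)
  codes <- matrix(as.integer(tokens), nrow = nchan)
  EMGSession(codes, samplingRate = meta$rate, subjectId = meta$subject,
             arm = meta$arm)
}

#' Stream a session as wire-protocol datagrams
#'
#' Thin live-transport layer: replays a single-arm session frame by frame
#' as 17-character datagrams onto a connection. With `port` given, a UDP
#' sender would bind the band's port (3333 left, 1812 right in the
#' acquisition setup); here any writable connection (file, socket) is
#' accepted, keeping the pipeline offline-first.
#'
#' @param record a single-arm [EMGSession-class].
#' @param con writable connection or file path.
#' @param marker start marker character.
#' @param maxFrames optional cap on frames streamed.
#' @return Invisibly, the number of frames written.
#' @export
streamSession <- function(record, con, marker = "A", maxFrames = Inf) {
  stopifnot(is(record, "EMGSession"))
  if (nrow(record@channels) != 4L)
    stopf("streaming operates on one band (4 channels) at a time")
  n <- min(ncol(record@channels), maxFrames)
  own <- FALSE
  if (is.character(con)) {
    con <- file(con, "w"); own <- TRUE
  }
  if (own) on.exit(close(con))
  for (t in seq_len(n))
    writeLines(encodeFrame(record@channels[, t], marker), con)
  invisible(as.integer(n))
}
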