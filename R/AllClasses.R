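#' @import methods
NULL

#' Multichannel electrogram recording
#'
#' Container for sampled intracardiac voltages with per-electrode geometry.
#' Signals are stored as a samples x channels matrix in mV. Each channel is
#' unipolar (one source electrode) or bipolar (two); electrode positions are
#' 3-D points in mm and may be static (one row) or time-varying (one row per
#' sample). A recording without geometry is permitted but distance-based
#' operations will refuse it.
#'
#' @slot signals numeric matrix, samples x channels, in mV.
#' @slot samplingRate sampling rate in samples/second (default 1000, so one
#'   sample corresponds to one millisecond).
#' @slot channelKind character vector, "unipolar" or "bipolar" per channel.
#' @slot catheter character vector mapping each channel to a catheter label
#'   (e.g. "PV", "CS").
#' @slot positions list (one element per channel) of lists of electrode
#'   position matrices (k x 3, k = 1 static or k = nSamples time-varying);
#'   may be an empty list per channel for geometry-free recordings.
#' @export
setClass("EgmRecording",
  representation(signals = "matrix", samplingRate = "numeric",
                 channelKind = "character", catheter = "character",
                 positions = "list"))

setValidity("EgmRecording", function(object) {
  msgs <- character(0)
  nc <- ncol(object@signals)
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a single positive number")
  if (is.null(colnames(object@signals)))
    msgs <- c(msgs, "signal columns must be named")
  if (length(object@channelKind) != nc || length(object@catheter) != nc ||
      length(object@positions) != nc)
    msgs <- c(msgs, "channelKind, catheter and positions must match channels")
  if (!all(object@channelKind %in% c("unipolar", "bipolar")))
    msgs <- c(msgs, "channelKind must be 'unipolar' or 'bipolar'")
  for (i in seq_len(nc)) {
    p <- object@positions[[i]]
    if (length(p) == 0L) next
    want <- if (object@channelKind[i] == "bipolar") 2L else 1L
    if (length(p) != want)
      msgs <- c(msgs, sprintf("channel %d: expected %d electrode position(s)",
                              i, want))
    for (m in p) {
      if (!is.matrix(m) || ncol(m) != 3L ||
          !(nrow(m) %in% c(1L, nrow(object@signals))))
        msgs <- c(msgs, sprintf("channel %d: positions must be 1x3 or n x 3",
                                i))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EgmRecording
#'
#' @param signals samples x channels numeric matrix (mV) with column names.
#' @param samplingRate samples/second.
#' @param kind per-channel "unipolar"/"bipolar" (recycled).
#' @param catheter per-channel catheter label (recycled).
#' @param positions per-channel list of electrode position matrices (mm);
#'   `NULL` for a geometry-free recording.
#' @return an [EgmRecording-class] object.
#' @export
EgmRecording <- function(signals, samplingRate = 1000, kind = "bipolar",
                         catheter = "PV", positions = NULL) {
  signals <- as.matrix(signals)
  if (is.null(colnames(signals)))
    colnames(signals) <- paste0("ch", seq_len(ncol(signals)))
  nc <- ncol(signals)
  if (is.null(positions)) positions <- rep(list(list()), nc)
  new("EgmRecording", signals = signals, samplingRate = samplingRate,
      channelKind = rep_len(kind, nc), catheter = rep_len(catheter, nc),
      positions = positions)
}

#' @describeIn EgmRecording number of samples per channel
#' @param x,object an `EgmRecording`.
#' @export
nSamples <- function(x) nrow(x@signals)

#' @describeIn EgmRecording number of channels
#' @export
nChannels <- function(x) ncol(x@signals)

#' @describeIn EgmRecording channel names
#' @export
channelNames <- function(x) colnames(x@signals)

#' @describeIn EgmRecording sampling rate in Hz
#' @export
samplingRate <- function(x) x@samplingRate

#' @describeIn EgmRecording signal matrix (samples x channels, mV)
#' @export
signalMatrix <- function(x) x@signals

#' @describeIn EgmRecording single-channel trace by index or name
#' @param channel channel index or name.
#' @export
channelTrace <- function(x, channel) as.numeric(x@signals[, channel])

#' @describeIn EgmRecording TRUE when no channel carries electrode positions
#' @export
isGeometryFree <- function(x) all(vapply(x@positions, length, 1L) == 0L)

#' Bipole (or electrode) reference position of a channel
#'
#' For bipolar channels the arithmetic mean of the two electrode positions
#' serves as the bipole location surrogate; time-varying positions are
#' averaged over time by default.
#'
#' @param x an `EgmRecording`.
#' @param channel channel index or name.
#' @param time_average average time-varying positions over samples.
#' @return length-3 numeric (mm).
#' @export
bipolePosition <- function(x, channel, time_average = TRUE) {
  if (is.character(channel)) channel <- match(channel, channelNames(x))
  p <- x@positions[[channel]]
  .stop_if_not(length(p) > 0, "recording is geometry-free for this channel")
  pts <- vapply(p, function(m) {
    if (nrow(m) == 1L || !time_average) m[1L, ] else colMeans(m)
  }, numeric(3))
  rowMeans(pts)
}

setMethod("show", "EgmRecording", function(object) {
  cat(sprintf("EgmRecording: %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nChannels(object), nSamples(object), samplingRate(object),
              nSamples(object) / samplingRate(object)))
  cat("  channels:", paste(head(channelNames(object), 8), collapse = ", "),
      if (nChannels(object) > 8) "..." else "", "\n")
  cat("  catheters:", paste(unique(object@catheter), collapse = ", "),
      if (isGeometryFree(object)) " (geometry-free)" else "", "\n")
  invisible(NULL)
})

#' Derive bipolar channels from unipolar pairs
#'
#' Each output trace is the first pair member minus the second
#' (proximal-minus-distal by convention; flip `sign`); the bipole position
#' is the arithmetic mean of the two electrode positions.
#'
#' @param rec an [EgmRecording-class] with unipolar channels.
#' @param pairing two-column integer matrix of unipolar channel indices.
#' @param names optional output channel names.
#' @param sign +1 for first-minus-second (default), -1 to flip polarity.
#' @return an `EgmRecording` of bipolar channels.
#' @export
deriveBipolar <- function(rec, pairing, names = NULL, sign = 1) {
  pairing <- matrix(as.integer(pairing), ncol = 2)
  kinds <- rec@channelKind[as.vector(pairing)]
  .stop_if_not(all(kinds == "unipolar"),
               "pairing must reference unipolar channels only")
  .stop_if_not(all(rec@catheter[pairing[, 1]] == rec@catheter[pairing[, 2]]),
               "paired electrodes must belong to the same catheter")
  sig <- sign * (rec@signals[, pairing[, 1], drop = FALSE] -
                 rec@signals[, pairing[, 2], drop = FALSE])
  if (is.null(names))
    names <- paste0(channelNames(rec)[pairing[, 1]], "-",
                    channelNames(rec)[pairing[, 2]])
  colnames(sig) <- names
  pos <- lapply(seq_len(nrow(pairing)), function(i) {
    p1 <- rec@positions[[pairing[i, 1]]]
    p2 <- rec@positions[[pairing[i, 2]]]
    if (length(p1) == 0L || length(p2) == 0L) list() else c(p1, p2)
  })
  EgmRecording(sig, samplingRate(rec), kind = "bipolar",
               catheter = rec@catheter[pairing[, 1]], positions = pos)
}
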