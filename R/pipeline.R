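# End-to-end orchestration: protocol inference, per-channel artifact
# removal, atrial detection, ERP estimation and restitution curves.

# Stimulus table with per-row S2 coupling interval (ms) filled in.
.stim_table <- function(protocol) {
  ann <- protocol$annotations
  ann$s2_ms <- NA_real_
  s2rows <- which(ann$label == "S2")
  ann$s2_ms[s2rows] <- protocol$s2_intervals_ms[ann$train_index[s2rows]]
  ann
}

#' Remove all stimulation artifacts and detect atrial activities per channel
#'
#' For one channel: chooses the stimulation template (shortest-S2,
#' QRS-free), subtracts it at every trusted stimulus, then searches the
#' interval after each stimulation peak for atrial activity with the NLEO
#' detector.
#'
#' @param x channel voltage trace.
#' @param stims stimulus table (from [segmentProtocol()] via the internal
#'   stim-table helper; columns `start`, `peak`, `end`, `label`,
#'   `train_index`, `s2_ms`).
#' @param k accepted threshold factor.
#' @param fs sampling rate (Hz).
#' @param qrs optional QRS fiducial table.
#' @param detrend remove baseline wander ([detrendWander()]) before
#'   template matching and detection.
#' @param lowpass_hz low-pass cutoff of the activity-detection prefilter.
#' @param ... forwarded to [detectAtrial()].
#' @return list: `detections` (one row per stimulus), `cleaned` trace
#'   (detrended, artifacts removed), `template`, `removal` diagnostics.
#' @export
analyzeChannel <- function(x, stims, k, fs = 1000, qrs = NULL,
                           detrend = TRUE, lowpass_hz = 150, ...) {
  stims <- stims[order(stims$peak), ]
  if (detrend) x <- detrendWander(x, fs)
  template <- selectTemplate(x, stims, qrs, fs)
  xc <- x
  removal <- vector("list", nrow(stims))
  for (i in seq_len(nrow(stims))) {
    res <- removeStimulus(xc, stims[i, ], template, fs)
    xc <- res$signal
    removal[[i]] <- data.frame(beat = i, scale = res$scale,
                               lag = res$lag, corr = res$corr,
                               flagged = res$flagged)
  }
  removal <- do.call(rbind, removal)
  # active support of the (trimmed) template, mapped onto each aligned
  # stimulus: defines the artifact onset (LAT reference) and end
  tw <- template$waveform
  act <- .active_support(tw)
  act_start0 <- act[1] - 1L
  act_end0 <- act[2] - 1L
  off0 <- template$onset_offset %||% 0L
  # low-pass once per channel; the per-window detector then runs without
  # its own prefilter
  xlp <- if (!is.null(lowpass_hz) && lowpass_hz < fs / 2)
    .butter_zerophase(xc, fs, lowpass_hz, "low") else xc
  ref_peak <- max(.moving_average(nleo(xlp), .ms2smp(5, fs)))
  dets <- vector("list", nrow(stims))
  for (i in seq_len(nrow(stims))) {
    next_onset <- if (i < nrow(stims)) stims$start[i + 1L] else length(xc)
    lag <- removal$lag[i]
    if (is.na(lag)) lag <- 0L
    onset <- stims$start[i] + off0 + lag + act_start0
    stim_end <- stims$start[i] + off0 + lag + act_end0 + 1L
    d <- detectAtrial(xc, stims[i, ], k, fs, next_onset = next_onset,
                      stim_end = stim_end, stim_onset = onset,
                      ref_peak = ref_peak, det_trace = xlp,
                      lowpass_hz = NULL, ...)
    d$train <- stims$train_index[i]
    d$label <- stims$label[i]
    d$s2_ms <- stims$s2_ms[i]
    d$stim_start <- stims$start[i]
    d$beat <- i
    dets[[i]] <- d
  }
  list(detections = do.call(rbind, dets), cleaned = xc,
       template = template, removal = removal)
}

#' Run the full segmentation pipeline on a recording
#'
#' Infers the pacing protocol from the signal alone, removes the
#' stimulation artifact on every non-stimulating channel, detects the
#' atrial response to each stimulus, estimates the effective refractory
#' period, and assembles amplitude, propagation-speed and LAT restitution
#' curves.
#'
#' @param rec an [EgmRecording-class].
#' @param qrs optional QRS fiducial table ([readQrsTable()]).
#' @param mesh optional [readSurfaceMesh()] result for geodesic
#'   inter-catheter distances.
#' @param exclude_neighbors omit the channels neighboring the stimulating
#'   bipole from the restitution curves (default, as their activity windows
#'   abut the artifact).
#' @param ... forwarded to [segmentProtocol()].
#' @return a `PipelineResult` list: `protocol`, `detections` (all
#'   channels), `erp`, `curves`, `channels` (analyzed channel indices).
#' @export
runPipeline <- function(rec, qrs = NULL, mesh = NULL,
                        exclude_neighbors = TRUE, ...) {
  fs <- samplingRate(rec)
  protocol <- segmentProtocol(rec, ...)
  stims <- .stim_table(protocol)
  chans <- setdiff(seq_len(nChannels(rec)), protocol$stim_channel)
  dets <- lapply(chans, function(ch) {
    d <- analyzeChannel(channelTrace(rec, ch), stims, protocol$k, fs,
                        qrs = qrs)$detections
    d$channel <- ch
    d$channel_name <- channelNames(rec)[ch]
    d$catheter <- rec@catheter[ch]
    d
  })
  detections <- do.call(rbind, dets)
  erp <- estimateErp(detections)
  curves <- buildCurves(detections, protocol, rec, mesh = mesh,
                        refractory = erp$refractory,
                        exclude_neighbors = exclude_neighbors)
  structure(list(protocol = protocol, detections = detections, erp = erp,
                 curves = curves, channels = chans),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  print(x$protocol)
  nd <- sum(x$detections$detected)
  cat(sprintf("  %d/%d activities detected on %d channels; ERP %s ms\n",
              nd, nrow(x$detections), length(x$channels),
              ifelse(is.na(x$erp$erp_ms), "not reached",
                     format(x$erp$erp_ms))))
  invisible(x)
}
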