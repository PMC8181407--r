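# Matched-filter elimination of the stimulation artifact and NLEO-based
# atrial activity detection in its temporal proximity, plus ERP estimation.

# Contiguous active support of an artifact waveform: expand around the
# maximum of the smoothed absolute deviation from the window's baseline
# (median) while it stays above `frac` of that maximum. Contiguity keeps
# isolated noise spikes from inflating the support; the baseline removal
# keeps residual wander offsets from doing the same. Returns c(lo, hi) as
# 1-based indices.
.active_support <- function(wave, frac = 0.1, smooth_smp = 3L) {
  wave <- wave - median(wave)
  s <- .moving_average(abs(wave), smooth_smp)
  m <- which.max(s)
  thr <- frac * s[m]
  lo <- m; hi <- m
  while (lo > 1L && s[lo - 1L] >= thr) lo <- lo - 1L
  while (hi < length(s) && s[hi + 1L] >= thr) hi <- hi + 1L
  # refine the edges on the raw trace: the moving average leaks the
  # support outward by up to half its width
  a <- abs(wave)
  thr_raw <- frac * max(a[lo:hi])
  inside <- which(a[lo:hi] >= thr_raw)
  c(lo + min(inside) - 1L, lo + max(inside) - 1L)
}

#' Choose a stimulation-signal template for a channel
#'
#' Iterates the S2 stimuli from the shortest coupling interval upward and
#' returns the first whose window does not intersect a QRS fiducial window.
#' The shortest-S2 window either contains no atrial answer (ERP reached) or
#' the answer farthest from the artifact, making it the cleanest template.
#'
#' @param x channel voltage trace.
#' @param stims annotation table of trusted stimuli for this recording
#'   (labels `S1`/`S2`), with per-train S2 coupling intervals available via
#'   `s2_ms` (added by [segmentProtocol()] consumers) or computed from peak
#'   spacing.
#' @param qrs optional QRS fiducial table ([readQrsTable()]).
#' @param fs sampling rate (Hz).
#' @param margin_ms margin kept around the artifact's active support.
#' @param active_frac amplitude fraction (of the smoothed window maximum)
#'   defining the artifact's contiguous active support; the returned
#'   waveform is trimmed to it so that correlation and scaling are not
#'   diluted by surrounding silence or noise.
#' @return a `TemplateChoice` list: `waveform` (trimmed to the active
#'   support plus margin), `window` (0-based `c(start, end)` in the
#'   trace), `onset_offset` (template start relative to the source
#'   stimulus' annotated window start, in samples), `beat` (row index into
#'   `stims`), `train_index`, `qrs_checked`.
#' @export
selectTemplate <- function(x, stims, qrs = NULL, fs = 1000, margin_ms = 2,
                           active_frac = 0.05) {
  s2 <- stims[stims$label == "S2", , drop = FALSE]
  .stop_if_not(nrow(s2) > 0, "no S2 stimulus available for template choice")
  coup <- if ("s2_ms" %in% names(s2) && !all(is.na(s2$s2_ms))) s2$s2_ms
          else vapply(seq_len(nrow(s2)), function(i) {
            prev <- stims$peak[stims$peak < s2$peak[i]]
            if (length(prev)) .smp2ms(s2$peak[i] - max(prev), fs)
            else NA_real_
          }, numeric(1))
  ord <- order(coup, na.last = TRUE)
  m <- .ms2smp(margin_ms, fs)
  for (i in ord) {
    w0 <- max(0L, s2$start[i] - m)
    w1 <- min(length(x), s2$end[i] + m)
    if (!is.null(qrs) && nrow(qrs) > 0 &&
        any(qrs$qrs_start < w1 & qrs$qrs_end > w0)) next
    wave <- x[(w0 + 1L):w1]
    act <- .active_support(wave, active_frac)
    t_lo <- max(1L, act[1] - m)
    t_hi <- min(length(wave), act[2] + m)
    return(structure(list(waveform = wave[t_lo:t_hi],
                          window = c(w0 + t_lo - 1L, w0 + t_hi),
                          onset_offset = (w0 + t_lo - 1L) - s2$start[i],
                          beat = which(stims$peak == s2$peak[i])[1],
                          train_index = s2$train_index[i],
                          qrs_checked = !is.null(qrs)),
                     class = "TemplateChoice"))
  }
  stop("no clean template: every S2 window overlaps a QRS complex")
}

#' Remove one stimulation artifact by matched-filter subtraction
#'
#' The template is aligned at the lag (within +-`max_shift_ms` of the
#' annotated stimulus) maximizing the normalized cross-correlation,
#' amplitude-scaled by the least-squares factor at that lag, and
#' subtracted. Samples from the annotated window start to the stimulation
#' peak are then replaced by linear interpolation between their boundary
#' values to avoid large derivatives that would distort the following
#' activity detection. If the best correlation falls below `min_corr` the
#' stimulus is left in place and flagged as a template mismatch.
#'
#' @param x channel voltage trace.
#' @param stim one-row stimulus annotation (`start`, `peak`, `end`).
#' @param template a [selectTemplate()] result.
#' @param fs sampling rate (Hz).
#' @param max_shift_ms alignment search half-range (ms).
#' @param min_corr normalized-correlation floor below which subtraction is
#'   refused.
#' @return list: `signal` (cleaned trace), `scale`, `lag` (samples),
#'   `corr`, `flagged`.
#' @export
removeStimulus <- function(x, stim, template, fs = 1000, max_shift_ms = 10,
                           min_corr = 0.5) {
  tw <- template$waveform
  lt <- length(tw)
  n <- length(x)
  # candidate 0-based start positions of the template in x, centered where
  # the (trimmed) template sat relative to its source annotation
  center <- stim$start + (template$onset_offset %||% 0L)
  shift <- .ms2smp(max_shift_ms, fs)
  offs <- seq(center - shift, center + shift)
  offs <- offs[offs >= 0 & offs + lt <= n]
  .stop_if_not(length(offs) > 0, "template longer than the search window")
  tnorm <- sqrt(sum(tw^2))
  best <- list(corr = -Inf, off = offs[1], scale = 0)
  for (o in offs) {
    seg <- x[(o + 1L):(o + lt)]
    cc <- sum(seg * tw) / (tnorm * sqrt(sum(seg^2)) + .Machine$double.eps)
    if (cc > best$corr)
      best <- list(corr = cc, off = o, scale = sum(seg * tw) / sum(tw^2))
  }
  if (best$corr < min_corr) {
    return(list(signal = x, scale = NA_real_, lag = NA_integer_,
                corr = best$corr, flagged = TRUE))
  }
  idx <- (best$off + 1L):(best$off + lt)
  x[idx] <- x[idx] - best$scale * tw
  # interpolate from the annotated window start through the stimulation
  # peak (the template's maximum-magnitude sample, mapped through the
  # alignment) to erase what the subtraction cannot
  peak_abs <- best$off + which.max(abs(tw)) - 1L
  i0 <- max(1L, stim$start)        # R index of sample before window start
  i1 <- min(n, max(stim$peak, peak_abs) + 2L)  # sample after the peak
  if (i1 - i0 > 1L) {
    x[i0:i1] <- seq(x[i0], x[i1], length.out = i1 - i0 + 1L)
  }
  list(signal = x, scale = best$scale, lag = best$off - center,
       corr = best$corr, flagged = FALSE)
}

#' Detect the atrial activity following one stimulus
#'
#' Runs the NLEO activity detector on the cleaned trace between the end of
#' the artifact's active support (where template subtraction and
#' interpolation leave residuals) and the next event onset (capped at a
#' physiological maximum activation delay). Among the threshold-crossing
#' segments the one
#' with the highest detection maximum defines the atrial window; the local
#' activation time (LAT) is the half-peak centroid of the detection pulse
#' minus the stimulus onset (the synthetic atrial waveform anchors its
#' ground-truth LAT through the same functional). When nothing crosses the threshold the beat is reported as not
#' detected (loss of capture). A detection is flagged untrusted
#' (`reason = "stim_overlap"`) when its energy peak lies within
#' `overlap_margin_ms` of the window start: the activity's maximum is then
#' clipped by (hidden under) the artifact window, the regime in which
#' heavily stimulus-overlapped activities become unrecoverable.
#'
#' @param x cleaned channel trace.
#' @param stim one-row stimulus annotation.
#' @param k threshold factor (accepted value from [estimateS1Bcl()]).
#' @param fs sampling rate (Hz).
#' @param next_onset 0-based start of the next event (bounds the search).
#' @param max_lat_ms physiological upper bound on the activation delay.
#' @param guard_ms search starts this long after the stimulation peak.
#' @param amp_margin_ms widen the detected window by this margin for the
#'   peak-to-peak amplitude measurement.
#' @param lowpass_hz,smooth_ms forwarded to [nleoSegments()].
#' @param stim_onset 0-based sample of the artifact onset (start of its
#'   active support) used as the LAT reference; defaults to the annotated
#'   window start.
#' @param stim_end 0-based sample bounding the artifact's active support
#'   (end of the aligned template's above-5%-amplitude region); defaults to
#'   the annotated window end.
#' @param overlap_margin_ms energy peaks within this margin of the window
#'   start are treated as clipped by the artifact window.
#' @param ref_peak optional channel-level reference detection maximum; a
#'   selected segment whose peak falls below `min_rel * ref_peak` is
#'   treated as numerical residue, not activity (guards exactly-silent
#'   windows after loss of capture against floating-point dust).
#' @param min_rel relative floor applied against `ref_peak`.
#' @param det_trace optional trace to run the detector on (e.g. the
#'   low-pass prefiltered cleaned signal, filtered once per channel);
#'   `lowpass_hz` should then be `NULL`. Amplitude is always measured on
#'   `x`.
#' @return one-row data frame: `detected`, `lat_ms`, `t_act` (0-based
#'   absolute detection-peak sample), `amplitude`, `win_start`, `win_end`,
#'   `reason`.
#' @export
detectAtrial <- function(x, stim, k, fs = 1000, next_onset = length(x),
                         max_lat_ms = 250, guard_ms = 2, amp_margin_ms = 5,
                         lowpass_hz = 150, smooth_ms = 5, stim_end = NULL,
                         stim_onset = NULL, overlap_margin_ms = 6,
                         ref_peak = NULL, min_rel = 1e-8,
                         det_trace = NULL) {
  if (is.null(stim_end)) stim_end <- stim$end
  if (is.null(stim_onset)) stim_onset <- stim$start
  w0 <- max(stim$peak, stim_end) + .ms2smp(guard_ms, fs)
  w1 <- min(next_onset, stim$start + .ms2smp(max_lat_ms, fs), length(x))
  none <- data.frame(detected = FALSE, lat_ms = NA_real_,
                     t_act = NA_integer_, amplitude = NA_real_,
                     win_start = NA_integer_, win_end = NA_integer_,
                     reason = "no_activity")
  if (w1 - w0 < .ms2smp(10, fs)) { none$reason <- "window_too_short"; return(none) }
  seg <- (det_trace %||% x)[(w0 + 1L):w1]
  det <- nleoSegments(seg, k, fs, smooth_ms = smooth_ms,
                      lowpass_hz = lowpass_hz)
  if (nrow(det$segments) == 0L) return(none)
  peaks <- det$detection[det$segments$peak + 1L]
  if (!is.null(ref_peak) && max(peaks) < min_rel * ref_peak) return(none)
  sel <- det$segments[which.max(peaks), ]
  # refine the activation sample: half-peak centroid of the energy pulse
  t_act <- w0 + .energy_centroid(det$detection, sel$peak + 1L,
                                 .ms2smp(10, fs)) - 1L
  a0 <- max(0L, w0 + sel$start - .ms2smp(amp_margin_ms, fs))
  a1 <- min(length(x), w0 + sel$end + .ms2smp(amp_margin_ms, fs))
  amp <- max(x[(a0 + 1L):a1]) - min(x[(a0 + 1L):a1])
  out <- data.frame(detected = TRUE,
                    lat_ms = .smp2ms(t_act - stim_onset, fs),
                    t_act = t_act, amplitude = amp,
                    win_start = w0 + sel$start, win_end = w0 + sel$end,
                    reason = "ok")
  if (t_act - w0 < .ms2smp(overlap_margin_ms, fs)) {
    out$detected <- FALSE
    out$lat_ms <- NA_real_
    out$t_act <- NA_integer_
    out$amplitude <- NA_real_
    out$reason <- "stim_overlap"
  }
  out
}

#' Estimate the effective refractory period from detected responses
#'
#' A pacing train is refractory when its S2 response amplitude drops below
#' 20% of the mean amplitude of the atrial responses to the S1 stimuli of
#' the same train (a missing S2 detection counts as refractory; trains with
#' no detected S1 response at all are indeterminate). The reported ERP is
#' the longest refractory S2 coupling interval, or `NA` when no train is
#' refractory.
#'
#' @param detections per-beat detection table with columns `train`,
#'   `label`, `s2_ms`, `amplitude`, `detected` (and optionally `channel`;
#'   refractoriness is then decided by channel majority).
#' @param frac amplitude threshold as a fraction of the mean S1 response.
#' @return list: `erp_ms`, `refractory` (logical per train),
#'   `indeterminate`.
#' @export
estimateErp <- function(detections, frac = 0.2) {
  if (!"channel" %in% names(detections)) detections$channel <- 1L
  trains <- sort(unique(detections$train))
  votes <- indet <- matrix(NA, length(trains),
                           length(unique(detections$channel)))
  chans <- sort(unique(detections$channel))
  for (ti in seq_along(trains)) {
    for (ci in seq_along(chans)) {
      d <- detections[detections$train == trains[ti] &
                      detections$channel == chans[ci], ]
      s1 <- d[d$label == "S1" & d$detected, ]
      s2 <- d[d$label == "S2", ]
      if (nrow(s1) == 0L || nrow(s2) == 0L) { indet[ti, ci] <- TRUE; next }
      indet[ti, ci] <- FALSE
      s2amp <- if (isTRUE(s2$detected[1])) s2$amplitude[1] else 0
      votes[ti, ci] <- s2amp < frac * mean(s1$amplitude)
    }
  }
  refractory <- vapply(seq_along(trains), function(ti) {
    v <- votes[ti, !is.na(votes[ti, ])]
    if (!length(v)) NA else mean(v) > 0.5
  }, logical(1))
  s2_of_train <- vapply(trains, function(tr) {
    v <- detections$s2_ms[detections$train == tr & detections$label == "S2"]
    if (length(v)) v[1] else NA_real_
  }, numeric(1))
  erp <- if (any(refractory %in% TRUE))
    max(s2_of_train[which(refractory %in% TRUE)], na.rm = TRUE)
  else NA_real_
  list(erp_ms = erp, refractory = refractory,
       indeterminate = apply(indet, 1L, function(z) all(z %in% TRUE)),
       trains = trains, s2_ms = s2_of_train)
}
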