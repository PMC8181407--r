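# Synthetic waveform templates. Only amplitude, duration and biphasic shape
# of the clinical waveforms are constrained; the functional forms are
# parametric stand-ins: per-phase exponential decay for the stimulus pulse
# and a smooth two-lobed (Gaussian-derivative-like) wave for the bipolar
# atrial activity.

#' Biphasic stimulation-artifact template
#'
#' Exponentially decaying biphasic pulse: a positive first phase of length
#' `stim_phase1`, then a negative second phase, total support exactly
#' `stim_duration`. Peak-to-peak amplitude equals `stim_amplitude`.
#'
#' @param spec a [waveformSpec()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of `stim_duration * fs / 1000` samples; attribute
#'   `peak` holds the 0-based index of the maximum-magnitude sample.
#' @export
stimulusTemplate <- function(spec, fs = 1000) {
  n <- .ms2smp(spec$stim_duration, fs)
  n1 <- .ms2smp(spec$stim_phase1, fs)
  .stop_if_not(n >= 2 && n1 >= 1 && n1 < n,
               "stimulus durations not representable at this sampling rate")
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  tau1 <- spec$stim_phase1 / 2
  tau2 <- (spec$stim_duration - spec$stim_phase1) / 3
  a <- spec$stim_amplitude / 2
  w <- numeric(n)
  ph1 <- t_ms < spec$stim_phase1
  w[ph1] <- a * exp(-t_ms[ph1] / tau1)
  w[!ph1] <- -a * exp(-(t_ms[!ph1] - spec$stim_phase1) / tau2)
  structure(w, peak = which.max(abs(w)) - 1L)
}

#' Bipolar atrial-activity template
#'
#' Smooth biphasic wave with a positive leading lobe and negative trailing
#' lobe separated by a single steepest-downstroke sample, which defines the
#' waveform's local-activation-time (LAT) reference point. The downstroke
#' sits at `atrial_lat_frac` of the duration, the support is exactly
#' `atrial_duration` (edges tapered to zero), and the peak-to-peak amplitude
#' equals `atrial_amplitude`. The LAT reference is invariant under amplitude
#' scaling.
#'
#' @param spec a [waveformSpec()].
#' @param fs sampling rate in Hz.
#' @return numeric vector with two 0-based index attributes: `downstroke`,
#'   the steepest-downstroke sample, and `lat_ref`, the sample the
#'   activity-detection series (low-pass, energy operator, smoothing; see
#'   [nleoSegments()]) annotates for this waveform. `lat_ref` anchors
#'   ground-truth placement so that simulator truth and detector output
#'   share one annotation convention; the two indices differ by at most a
#'   couple of samples.
#' @export
atrialTemplate <- function(spec, fs = 1000) {
  n <- .ms2smp(spec$atrial_duration, fs)
  .stop_if_not(n >= 5, "atrial duration not representable at sampling rate")
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  t0 <- spec$atrial_lat_frac * spec$atrial_duration
  s1 <- t0 / 3
  s2 <- (spec$atrial_duration - t0) / 3
  sig <- ifelse(t_ms < t0, s1, s2)
  w <- ((t0 - t_ms) / sig) * exp(-(t_ms - t0)^2 / (2 * sig^2))
  # taper so the support ends exactly at the window edges
  ramp <- w[1L] + (t_ms - t_ms[1L]) / (t_ms[n] - t_ms[1L]) * (w[n] - w[1L])
  w <- w - ramp
  p2p <- max(w) - min(w)
  if (p2p > 0) w <- w * spec$atrial_amplitude / p2p
  downstroke <- as.integer(which.min(diff(w)) - 1L)  # 0-based
  pad <- numeric(max(50L, n))
  e <- .atrial_detection_series(c(pad, w, pad), fs)
  lat_ref <- as.integer(.energy_centroid(e, max_halfwidth = .ms2smp(10, fs)) -
                        length(pad) - 1L)  # 0-based
  structure(w, downstroke = downstroke, lat_ref = lat_ref)
}
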