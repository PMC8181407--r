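# Clinical-spectrum noise synthesis, baseline wander, and SNR scaling.

#' Noise specification
#'
#' Either a measured reference segment (its magnitude spectrum is reused
#' with random phases) or an analytic stand-in spectrum: 1/f^alpha plus a
#' white floor and a mains harmonic. The stand-in replaces the unavailable
#' clinical noise recording and must be declared alongside any reported
#' results.
#'
#' @param spectrum_source `"standin"` or `"reference_segment"`.
#' @param reference numeric reference noise segment (>= 1 s) when
#'   `spectrum_source = "reference_segment"`.
#' @param alpha 1/f exponent of the stand-in.
#' @param f_min lower band edge of the 1/f component (Hz).
#' @param f_max upper band edge of the 1/f component and white floor (Hz).
#'   Clinical electrograms are low-pass filtered by the recording chain, so
#'   noise reconstructed from them is band-limited; 250 Hz is a typical
#'   clinical cutoff.
#' @param white_rel_db white-floor power relative to the 1/f component (dB).
#' @param mains_hz powerline frequency (Hz).
#' @param mains_rel_db mains-harmonic power relative to the 1/f component
#'   (dB).
#' @return a `NoiseSpec` list.
#' @export
noiseSpec <- function(spectrum_source = c("standin", "reference_segment"),
                      reference = NULL, alpha = 1, f_min = 1, f_max = 250,
                      white_rel_db = -20, mains_hz = 50,
                      mains_rel_db = -10) {
  spectrum_source <- match.arg(spectrum_source)
  structure(list(spectrum_source = spectrum_source, reference = reference,
                 alpha = alpha, f_min = f_min, f_max = f_max,
                 white_rel_db = white_rel_db, mains_hz = mains_hz,
                 mains_rel_db = mains_rel_db),
            class = "NoiseSpec")
}

#' Synthesize noise with a prescribed magnitude spectrum
#'
#' Builds the one-sided magnitude spectrum (from the reference segment,
#' resampled onto the requested length, or from the analytic stand-in),
#' draws phases uniformly at random, and inverse-transforms. Deterministic
#' under a fixed seed; the mean power is set by the magnitudes alone. The
#' output is zero-mean (the DC bin is zeroed).
#'
#' @param length output length in samples.
#' @param fs sampling rate in Hz.
#' @param spec a [noiseSpec()].
#' @param seed RNG seed.
#' @return numeric noise series (arbitrary scale; see [scaleNoiseToSnr()]).
#' @export
noiseFromSpectrum <- function(length, fs, spec = noiseSpec(), seed = NULL) {
  .stop_if_not(length > 0, "length must be positive")
  n <- as.integer(length)
  nh <- n %/% 2L
  freqs <- (seq_len(nh)) * fs / n
  if (spec$spectrum_source == "reference_segment") {
    ref <- spec$reference
    .stop_if_not(!is.null(ref) && base::length(ref) >= fs,
                 "reference segment must be at least 1 s long")
    ref <- ref - mean(ref)
    nr <- base::length(ref)
    rmag <- Mod(fft(ref))[seq_len(nr %/% 2L)]
    rfreq <- (seq_len(nr %/% 2L)) * fs / nr
    mag2 <- stats::approx(rfreq, rmag^2 / nr, xout = freqs, rule = 2)$y
  } else {
    mag2 <- numeric(nh)
    f_max <- spec$f_max %||% (fs / 2)
    band <- freqs >= spec$f_min & freqs <= f_max
    mag2[band] <- 1 / freqs[band]^spec$alpha
    p_band <- sum(mag2)
    if (p_band == 0) p_band <- 1
    mag2[freqs <= f_max] <- mag2[freqs <= f_max] +
      p_band * 10^(spec$white_rel_db / 10) / max(1L, sum(freqs <= f_max))
    k_mains <- which.min(abs(freqs - spec$mains_hz))
    mag2[k_mains] <- mag2[k_mains] + p_band * 10^(spec$mains_rel_db / 10)
  }
  mag <- sqrt(pmax(mag2, 0))
  if (all(mag == 0)) return(numeric(n))
  x <- .with_seed(seed, {
    ph <- runif(nh, 0, 2 * pi)
    spec_full <- complex(length.out = n)
    spec_full[2:(nh + 1L)] <- mag * exp(1i * ph)
    # mirror for a real-valued series; Nyquist bin (even n) forced real
    if (n %% 2L == 0L) {
      spec_full[nh + 1L] <- mag[nh]
      spec_full[seq.int(n, n - nh + 2L)] <- Conj(spec_full[2:nh])
    } else {
      spec_full[seq.int(n, n - nh + 1L)] <- Conj(spec_full[2:(nh + 1L)])
    }
    Re(fft(spec_full, inverse = TRUE)) / n
  })
  x - mean(x)
}

#' Baseline wander
#'
#' Sum of sinusoids on a 0.001-5 Hz frequency grid with uniform random
#' phases, rescaled once so the composite peak amplitude equals twice the
#' atrial activity amplitude.
#'
#' @param length output length in samples.
#' @param fs sampling rate in Hz.
#' @param atrial_amplitude atrial activity amplitude in mV.
#' @param seed RNG seed.
#' @param f_grid component frequencies (Hz).
#' @return numeric wander series of peak amplitude `2 * atrial_amplitude`.
#' @export
baselineWander <- function(length, fs, atrial_amplitude = 2, seed = NULL,
                           f_grid = c(0.001, seq(0.25, 5, by = 0.25))) {
  .stop_if_not(length > 0, "length must be positive")
  if (atrial_amplitude == 0) return(numeric(length))
  t <- (seq_len(length) - 1) / fs
  x <- .with_seed(seed, {
    ph <- runif(base::length(f_grid), 0, 2 * pi)
    rowSums(vapply(seq_along(f_grid),
                   function(i) sin(2 * pi * f_grid[i] * t + ph[i]),
                   numeric(base::length(t))))
  })
  x * (2 * atrial_amplitude / max(abs(x)))
}

#' Mean power of a signal
#'
#' Whole-record mean squared amplitude by default, matching the plain
#' power-ratio SNR definition. `active_only = TRUE` instead measures power
#' over the active support only (samples where the clean signal's envelope
#' exceeds a fraction of its maximum), which yields a much larger signal
#' power on a mostly-silent S1S2 record and correspondingly stronger noise
#' at the same nominal SNR.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param active_only restrict to the active support.
#' @param frac envelope threshold as a fraction of the envelope maximum.
#' @param win_ms envelope window (ms).
#' @return mean squared amplitude.
#' @export
signalPower <- function(x, fs = 1000, active_only = FALSE, frac = 0.01,
                        win_ms = 10) {
  if (!active_only) return(mean(x^2))
  env <- .envelope(x, .ms2smp(win_ms, fs))
  act <- env > frac * max(env)
  if (!any(act)) return(0)
  mean(x[act]^2)
}

#' Scale noise to a target signal-to-noise ratio
#'
#' Returns `n * noise` with the amplitude factor
#' `n = 10^((SNR_current - SNR_target) / 20)`, where
#' `SNR_current = 10 * log10(P_signal / P_noise)` in dB. After scaling,
#' `10 * log10(P_signal / P_scaled)` equals the target within numerical
#' precision. Signal and noise power are whole-series mean squared
#' amplitudes (see [signalPower()]).
#'
#' @param signal clean signal (defines `P_signal`).
#' @param noise noise series with nonzero power.
#' @param target_snr_db desired SNR in dB.
#' @param fs sampling rate in Hz.
#' @param signal_power optional precomputed signal power (overrides
#'   `signal`).
#' @return scaled noise with attribute `scale` = the amplitude factor.
#' @export
scaleNoiseToSnr <- function(signal, noise, target_snr_db, fs = 1000,
                            signal_power = NULL) {
  p_n <- mean(noise^2)
  .stop_if_not(p_n > 0, "noise has zero power")
  p_s <- if (is.null(signal_power)) signalPower(signal, fs) else signal_power
  .stop_if_not(p_s > 0, "signal has zero power")
  snr_cur <- 10 * log10(p_s / p_n)
  sc <- 10^((snr_cur - target_snr_db) / 20)
  structure(sc * noise, scale = sc)
}

#' Add spectrum-matched noise and baseline wander to a synthetic protocol
#'
#' Each channel receives an independent noise realization scaled to the
#' target SNR against that channel's clean active-support power. Baseline
#' wander is added after SNR scaling and excluded from the noise power.
#'
#' @param sim a `SyntheticProtocol`.
#' @param snr_db target SNR in dB (`NULL` adds no spectrum noise).
#' @param noise_spec a [noiseSpec()].
#' @param seed RNG seed (per-channel seeds are derived from it).
#' @param wander add baseline wander.
#' @return the `SyntheticProtocol` with a noisy recording (the clean
#'   recording is retained as `$clean`).
#' @export
addProtocolNoise <- function(sim, snr_db, noise_spec = noiseSpec(),
                             seed = 1L, wander = TRUE) {
  rec <- sim$recording
  n <- nSamples(rec); fs <- samplingRate(rec)
  sig <- signalMatrix(rec)
  out <- sig
  for (ch in seq_len(ncol(sig))) {
    ch_seed <- (seed * 1000L + ch) %% .Machine$integer.max
    if (!is.null(snr_db)) {
      nz <- noiseFromSpectrum(n, fs, noise_spec, seed = ch_seed)
      out[, ch] <- out[, ch] + scaleNoiseToSnr(sig[, ch], nz, snr_db, fs)
    }
    if (wander) {
      out[, ch] <- out[, ch] +
        baselineWander(n, fs, sim$waveforms$atrial_amplitude,
                       seed = ch_seed + 1L)
    }
  }
  sim$clean <- rec
  rec@signals <- out
  sim$recording <- rec
  sim
}
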