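# Synthetic S1S2 protocol generation with full ground truth.

.fiber_effective_distance <- function(delta, fiber_angle_deg, anisotropy) {
  u <- c(cos(fiber_angle_deg * pi / 180), sin(fiber_angle_deg * pi / 180), 0)
  d_par <- sum(delta * u)
  d_perp <- sqrt(max(sum(delta^2) - d_par^2, 0))
  sqrt(d_par^2 + (anisotropy * d_perp)^2)
}

#' Assign local activation times over the catheter layout
#'
#' Activation spreads from the stimulating bipole as an elliptic anisotropic
#' wavefront: the distance component transverse to the fiber axis is
#' stretched by the anisotropy factor and the effective path length is
#' divided by the (rate-dependent) conduction velocity. The stimulating
#' bipole has LAT 0 by convention.
#'
#' @param layout a [catheterLayout()].
#' @param model a [restitutionModel()].
#' @param s2 S2 coupling interval in ms (`Inf` for baseline/S1 velocity).
#' @param erp effective refractory period anchoring the restitution curves.
#' @return named numeric vector of LATs in ms, one per bipole channel.
#' @export
assignLats <- function(layout, model, s2 = Inf, erp = 200) {
  geo <- bipoleGeometry(layout)
  cv <- cvAt(model, s2, erp)
  stim <- geo$centers[geo$stim, ]
  lats <- apply(geo$centers, 1L, function(p) {
    d_eff <- .fiber_effective_distance(p - stim, model$fiber_angle_deg,
                                       model$anisotropy)
    1000 * d_eff / cv
  })
  lats[geo$stim] <- 0
  lats
}

# Stimulus-artifact attenuation with distance from the stimulating bipole.
.artifact_gain <- function(dist_mm, d0 = 20) 1 / (1 + dist_mm / d0)

#' Build a complete synthetic S1S2 protocol recording
#'
#' Lays out `n_s1_per_train` S1 stimuli at the basic cycle length followed
#' by one S2 stimulus per train, separated by the inter-train gap. Every
#' channel receives the stimulation artifact (attenuated with distance from
#' the stimulating bipole); every captured stimulus (S1 always, S2 only when
#' its coupling interval reaches the ERP) is followed on each non-stimulating
#' channel by the atrial waveform placed at the channel's LAT with the
#' restitution amplitude. The ground truth records, per channel and beat,
#' the true activation sample, LAT, amplitude, capture flag, and the overlap
#' fraction between the atrial waveform and the stimulation artifact window.
#'
#' @param spec a [protocolSpec()].
#' @param layout a [catheterLayout()].
#' @param waveforms a [waveformSpec()].
#' @param model a [restitutionModel()].
#' @param fs sampling rate in Hz.
#' @param pad_ms silence before the first and after the last event (ms).
#' @return list of class `SyntheticProtocol` with elements `recording`
#'   ([EgmRecording-class]), `truth` (data frame: `channel`, `channel_name`,
#'   `catheter`, `train`, `beat`, `label`, `s2_ms`, `stim_start`,
#'   `capture`, `lat_ms`, `t_act` (0-based activation sample), `amplitude`,
#'   `overlap`), `stim_times` (0-based stimulus onsets), and the input
#'   specs.
#' @export
buildProtocol <- function(spec = protocolSpec(), layout = catheterLayout(),
                          waveforms = waveformSpec(),
                          model = restitutionModel(), fs = 1000,
                          pad_ms = 300) {
  geo <- bipoleGeometry(layout)
  nch <- nrow(geo$centers)
  stim_t <- stimulusTemplate(waveforms, fs)
  atr_t <- atrialTemplate(waveforms, fs)
  lat_ref <- attr(atr_t, "lat_ref")

  # stimulus schedule (ms)
  t <- pad_ms
  stim_ms <- numeric(0); stim_label <- character(0)
  stim_train <- integer(0); stim_s2 <- numeric(0)
  for (tr in seq_along(spec$s2_intervals)) {
    s1s <- t + (seq_len(spec$n_s1_per_train) - 1) * spec$s1_bcl
    s2 <- s1s[length(s1s)] + spec$s2_intervals[tr]
    stim_ms <- c(stim_ms, s1s, s2)
    stim_label <- c(stim_label, rep("S1", length(s1s)), "S2")
    stim_train <- c(stim_train, rep(tr, length(s1s) + 1L))
    stim_s2 <- c(stim_s2, rep(NA_real_, length(s1s)), spec$s2_intervals[tr])
    t <- s2 + spec$inter_train_gap
  }
  total_ms <- t - spec$inter_train_gap + max(spec$s1_bcl, 2 * pad_ms)
  n <- .ms2smp(total_ms, fs)
  sig <- matrix(0, n, nch, dimnames = list(NULL, geo$names))

  stim_pos <- geo$centers[geo$stim, ]
  dists <- apply(geo$centers, 1L, function(p) sqrt(sum((p - stim_pos)^2)))
  gains <- .artifact_gain(dists)

  add_wave <- function(ch, at0, w) {
    idx <- at0 + seq_along(w)  # at0 is 0-based start -> R indices at0+1...
    keep <- idx >= 1L & idx <= n
    sig[idx[keep], ch] <<- sig[idx[keep], ch] + w[keep]
  }

  truth <- vector("list", length(stim_ms))
  stim_dur_ms <- waveforms$stim_duration
  for (i in seq_along(stim_ms)) {
    st0 <- .ms2smp(stim_ms[i], fs)
    for (ch in seq_len(nch)) add_wave(ch, st0, gains[ch] * stim_t)
    is_s2 <- stim_label[i] == "S2"
    s2_val <- if (is_s2) stim_s2[i] else Inf
    capture <- !is_s2 || stim_s2[i] >= spec$erp
    lats <- assignLats(layout, model, s2 = s2_val, erp = spec$erp)
    amp <- ampAt(model, s2_val, spec$erp)
    rows <- lapply(seq_len(nch), function(ch) {
      if (ch == geo$stim) return(NULL)  # pacing site carries no response
      lat <- lats[ch]
      t_act <- st0 + .ms2smp(lat, fs)
      if (capture) {
        w <- atr_t * (amp / waveforms$atrial_amplitude)
        add_wave(ch, t_act - lat_ref, w)
      }
      atr_start_ms <- .smp2ms(t_act - lat_ref, fs)
      ovl <- max(0, min(1, (.smp2ms(st0, fs) + stim_dur_ms - atr_start_ms) /
                             waveforms$atrial_duration))
      data.frame(channel = ch, channel_name = geo$names[ch],
                 catheter = geo$catheter[ch], train = stim_train[i],
                 beat = i, label = stim_label[i],
                 s2_ms = if (is_s2) stim_s2[i] else NA_real_,
                 stim_start = st0, capture = capture, lat_ms = lat,
                 t_act = if (capture) t_act else NA_integer_,
                 amplitude = if (capture) amp else NA_real_,
                 overlap = if (capture) ovl else NA_real_)
    })
    truth[[i]] <- do.call(rbind, rows)
  }
  truth <- do.call(rbind, truth)

  positions <- lapply(geo$electrodes, function(m) {
    lapply(seq_len(nrow(m)), function(r) m[r, , drop = FALSE])
  })
  rec <- EgmRecording(sig, samplingRate = fs, kind = "bipolar",
                      catheter = geo$catheter, positions = positions)
  structure(list(recording = rec, truth = truth,
                 stim_times = .ms2smp(stim_ms, fs),
                 stim_label = stim_label, stim_train = stim_train,
                 spec = spec, layout = layout, waveforms = waveforms,
                 model = model),
            class = "SyntheticProtocol")
}

#' @export
print.SyntheticProtocol <- function(x, ...) {
  cat(sprintf(paste0("SyntheticProtocol: %d trains, %d stimuli, ",
                     "%d channels, %.1f s @ %g Hz\n"),
              length(x$spec$s2_intervals), length(x$stim_times),
              nChannels(x$recording),
              nSamples(x$recording) / samplingRate(x$recording),
              samplingRate(x$recording)))
  invisible(x)
}

#' Insert randomly timed extra beats
#'
#' Adds copies of the atrial waveform (at baseline amplitude, simultaneously
#' on all non-stimulating channels, so they are morphologically
#' indistinguishable from paced responses) at uniform-random times that
#' avoid +-`avoid_ms` around existing events. Ground truth labels them
#' `extra`.
#'
#' @param sim a `SyntheticProtocol` from [buildProtocol()].
#' @param n_beats number of beats to insert.
#' @param seed RNG seed.
#' @param avoid_ms guard interval around existing events (ms).
#' @param max_tries placement retries before giving up with an error.
#' @return the modified `SyntheticProtocol`.
#' @export
insertExtraBeats <- function(sim, n_beats, seed = NULL, avoid_ms = 50,
                             max_tries = 1000L) {
  if (n_beats == 0) return(sim)
  fs <- samplingRate(sim$recording)
  atr_t <- atrialTemplate(sim$waveforms, fs)
  lat_ref <- attr(atr_t, "lat_ref")
  n <- nSamples(sim$recording)
  geo <- bipoleGeometry(sim$layout)
  busy <- c(sim$stim_times, sim$truth$t_act[!is.na(sim$truth$t_act)])
  guard <- .ms2smp(avoid_ms, fs)
  sig <- signalMatrix(sim$recording)
  placed <- integer(0)
  .with_seed(seed, {
    for (b in seq_len(n_beats)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- as.integer(floor(runif(1, guard, n - guard - length(atr_t))))
        if (all(abs(cand - busy) > guard) &&
            (length(placed) == 0L || all(abs(cand - placed) > guard))) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("protocol too dense to place extra beats")
      placed <- c(placed, cand)
    }
  })
  extra_rows <- vector("list", length(placed))
  for (b in seq_along(placed)) {
    at0 <- placed[b]
    for (ch in seq_len(nChannels(sim$recording))) {
      if (ch == geo$stim) next
      idx <- (at0 - lat_ref) + seq_along(atr_t)
      keep <- idx >= 1L & idx <= n
      sig[idx[keep], ch] <- sig[idx[keep], ch] + atr_t[keep]
    }
    extra_rows[[b]] <- data.frame(channel = NA_integer_,
                                  channel_name = "all", catheter = NA,
                                  train = NA_integer_, beat = NA_integer_,
                                  label = "extra", s2_ms = NA_real_,
                                  stim_start = NA_integer_, capture = TRUE,
                                  lat_ms = NA_real_, t_act = at0,
                                  amplitude = sim$model$amp0,
                                  overlap = NA_real_)
  }
  sim$recording@signals <- sig
  sim$truth <- rbind(sim$truth, do.call(rbind, extra_rows))
  sim
}
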