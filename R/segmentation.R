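# Protocol inference from the signal alone: stimulating-channel detection,
# iterative threshold factor, S1 BCL via the inter-peak interval histogram,
# pacing-train splitting by deterministic 2-means, stimulus validation
# (conditions C1-C5) and S1/S2 tagging.

#' Identify the stimulating channel
#'
#' The stimulation artifact has the highest amplitude in the stimulating
#' channel and decays with distance, so the runner-up must be a spatial
#' neighbor. Channels are scanned down the amplitude ranking until a channel
#' and the next-ranked one are neighbors, which makes the choice robust to a
#' single high-amplitude artifact in a non-neighboring channel.
#'
#' @param rec an [EgmRecording-class] with geometry (or
#'   `neighbor_matrix`).
#' @param neighbor_matrix optional logical adjacency matrix overriding the
#'   geometric neighbor definition.
#' @return stimulating channel index.
#' @export
findStimChannel <- function(rec, neighbor_matrix = NULL) {
  nc <- nChannels(rec)
  .stop_if_not(nc >= 2, "need at least two channels")
  fs <- samplingRate(rec)
  amp <- apply(signalMatrix(rec), 2L,
               function(x) { xd <- detrendWander(x, fs); max(xd) - min(xd) })
  if (is.null(neighbor_matrix)) {
    .stop_if_not(!isGeometryFree(rec),
                 "geometry (or neighbor_matrix) required")
    pos <- t(vapply(seq_len(nc), function(i) bipolePosition(rec, i),
                    numeric(3)))
    neighbor_matrix <- matrix(FALSE, nc, nc)
    for (cath in unique(rec@catheter)) {
      idx <- which(rec@catheter == cath)
      if (length(idx) < 2) next
      d <- as.matrix(dist(pos[idx, , drop = FALSE]))
      diag(d) <- Inf
      lim <- 1.25 * min(d)
      neighbor_matrix[idx, idx] <- d <= lim
    }
  }
  ord <- order(amp, decreasing = TRUE)
  for (i in seq_len(nc - 1L)) {
    if (neighbor_matrix[ord[i], ord[i + 1L]]) return(ord[i])
  }
  stop("stimulating catheter not identifiable")
}

# Non-maximum suppression: keep the strongest peak within any min_sep
# window, so one stimulus yields one candidate even when filter ringing
# splits its detection response into several threshold runs.
.nms_segments <- function(det, segments, min_sep_smp) {
  if (nrow(segments) < 2L) return(segments)
  if (nrow(segments) > 4000L) {
    # pre-reduce dense segment sets: keep the strongest peak per half-window
    # bin before the exact greedy pass
    bin <- segments$peak %/% max(1L, min_sep_smp %/% 2L)
    keep <- unlist(lapply(split(seq_len(nrow(segments)), bin), function(i)
      i[which.max(det[segments$peak[i] + 1L])]), use.names = FALSE)
    segments <- segments[sort(keep), , drop = FALSE]
  }
  ord <- order(det[segments$peak + 1L], decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(segments$peak[i] - segments$peak[kept]) >= min_sep_smp))
      kept <- c(kept, i)
  }
  segments[sort(kept), , drop = FALSE]
}

# Histogram of inter-peak intervals: 1-sample bins merged greedily (largest
# bin absorbs bins within +-merge_smp), returning merged bins sorted by
# count.
.interval_histogram <- function(peaks_smp, max_lag_smp, merge_smp = 10L) {
  p <- sort(peaks_smp)
  n <- length(p)
  if (n < 2L) return(NULL)
  hi <- findInterval(p + max_lag_smp, p)
  d <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    if (hi[i] > i) d[[i]] <- p[(i + 1L):hi[i]] - p[i]
  }
  d <- unlist(d, use.names = FALSE)
  d <- d[d > 0]
  if (length(d) == 0L) return(NULL)
  tab <- table(d)
  vals <- as.numeric(names(tab))
  cnts <- as.numeric(tab)
  merged_v <- numeric(0); merged_c <- numeric(0)
  while (length(vals)) {
    i <- which.max(cnts)
    near <- abs(vals - vals[i]) <= merge_smp
    merged_v <- c(merged_v, vals[i])
    merged_c <- c(merged_c, sum(cnts[near]))
    vals <- vals[!near]; cnts <- cnts[!near]
  }
  ord <- order(merged_c, decreasing = TRUE)
  data.frame(interval = merged_v[ord], count = merged_c[ord])
}

#' Estimate the S1 basic cycle length and detection threshold factor
#'
#' Iterates the threshold factor k upward from a low initial value. At each
#' k the high-passed stimulation-channel trace is segmented with the
#' bior1.5 wavelet detector, the histogram of all inter-peak intervals is
#' built, and the three most frequent intervals are identified. The
#' estimate is accepted when the 2nd and 3rd most frequent intervals are
#' integer multiples of the 1st within 10 samples; the most frequent
#' interval is the S1 basic cycle length. If the condition is never met a
#' warning is issued and the last iterate returned flagged unconverged.
#'
#' @param rec an [EgmRecording-class].
#' @param k0 initial threshold factor.
#' @param dk increment per iteration.
#' @param max_iter maximum number of iterations.
#' @param stim_channel stimulating channel (found automatically when
#'   `NULL`).
#' @param max_lag_ms histogram support (ms).
#' @param max_peaks iterations producing more candidate peaks than this are
#'   skipped (threshold clearly below the noise floor).
#' @param min_sep_ms minimum peak separation (ms): within this window only
#'   the strongest detection peak is kept, so one stimulus contributes one
#'   peak; well below any plausible coupling interval.
#' @return list with `k`, `s1_bcl_ms`, `detector` (the accepted
#'   [waveletSegments()] output), `stim_channel`, `converged`.
#' @export
estimateS1Bcl <- function(rec, k0 = 0.01, dk = 0.01, max_iter = 1000L,
                          stim_channel = NULL, max_lag_ms = 5000,
                          max_peaks = 3000L, min_sep_ms = 50) {
  fs <- samplingRate(rec)
  if (is.null(stim_channel)) stim_channel <- findStimChannel(rec)
  hp <- highpassStim(channelTrace(rec, stim_channel), fs)
  tol <- .ms2smp(10, fs)  # 10-sample tolerance at the native rate
  # the wavelet detection series does not depend on k; compute it once and
  # only re-threshold per iteration
  base_det <- waveletSegments(hp, k0, fs)
  det_sd <- sd(base_det$detection)
  min_sep <- .ms2smp(min_sep_ms, fs)
  last <- NULL
  any_peaks <- FALSE
  for (it in seq_len(max_iter)) {
    k <- k0 + (it - 1L) * dk
    segs <- .runs_above(base_det$detection, k * det_sd)
    if (nrow(segs) > 10L * max_peaks) next  # far below the noise floor
    segs <- .nms_segments(base_det$detection, segs, min_sep)
    pk <- segs$peak
    if (length(pk) >= 3L) any_peaks <- TRUE
    if (length(pk) < 3L || length(pk) > max_peaks) next
    hist <- .interval_histogram(pk, .ms2smp(max_lag_ms, fs), tol)
    if (is.null(hist) || nrow(hist) < 3L) next
    top <- hist$interval[1:3]
    mult <- round(top[2:3] / top[1])
    ok <- all(mult >= 2) && all(abs(top[2:3] - mult * top[1]) <= tol)
    last <- list(k = k,
                 s1_bcl_ms = .smp2ms(top[1], fs),
                 detector = .detector_output(base_det$detection, segs,
                                             k * det_sd, k),
                 stim_channel = stim_channel, converged = ok)
    if (ok) return(last)
  }
  if (!any_peaks) stop("fewer than 3 stimulation peaks detected at any k")
  warning("S1 cycle length estimation did not converge within max_iter")
  if (is.null(last)) {
    k <- k0 + (max_iter - 1L) * dk
    segs <- .nms_segments(base_det$detection,
                          .runs_above(base_det$detection, k * det_sd),
                          min_sep)
    hist <- .interval_histogram(segs$peak, .ms2smp(max_lag_ms, fs), tol)
    last <- list(k = k,
                 s1_bcl_ms = if (!is.null(hist)) .smp2ms(hist$interval[1], fs)
                             else NA_real_,
                 detector = .detector_output(base_det$detection, segs,
                                             k * det_sd, k),
                 stim_channel = stim_channel, converged = FALSE)
  }
  last
}

# Deterministic 2-means on a numeric vector, initialized at min and max.
.two_means <- function(x, max_iter = 100L) {
  c1 <- min(x); c2 <- max(x)
  for (i in seq_len(max_iter)) {
    assign2 <- abs(x - c2) < abs(x - c1)
    n1 <- mean(x[!assign2]); n2 <- mean(x[assign2])
    if (isTRUE(all.equal(c(c1, c2), c(n1, n2)))) break
    c1 <- n1; c2 <- n2
  }
  list(centers = c(c1, c2), long = assign2)
}

#' Split detected peaks into pacing trains
#'
#' Classifies inter-peak intervals with a deterministic 2-means clustering
#' (initialized at the extreme values): the long-interval cluster marks
#' train boundaries. The number of S1 stimuli per train is the mode of the
#' S1-interval run lengths plus one, and each train's S2 coupling interval
#' is sought within a window of one S1 cycle length after the last S1.
#' A warning flags unreliable separation when the long-cluster centroid is
#' below 1.2 times the S1 cycle length.
#'
#' @param peak_times_ms sorted stimulus peak times in ms.
#' @param s1_bcl S1 basic cycle length in ms.
#' @param tol_ms tolerance for recognizing an S1 interval (ms).
#' @return list with `trains` (list of peak-index vectors),
#'   `n_s1_per_train`, `s2_intervals_ms` (NA when not found),
#'   `inter_train_gap_ms`, `centers`.
#' @export
splitTrains <- function(peak_times_ms, s1_bcl, tol_ms = 10) {
  peak_times_ms <- sort(peak_times_ms)
  d <- diff(peak_times_ms)
  .stop_if_not(length(unique(round(d))) >= 2,
               "need at least two distinct inter-peak intervals")
  km <- .two_means(d)
  if (max(km$centers) < 1.2 * s1_bcl)
    warning("unreliable train separation: inter-train intervals below ",
            "1.2 x S1 cycle length")
  boundary <- which(km$long)  # d[i] long => trains split between i, i+1
  starts <- c(1L, boundary + 1L)
  ends <- c(boundary, length(peak_times_ms))
  trains <- Map(seq, starts, ends)
  run_lengths <- vapply(trains, function(idx) {
    if (length(idx) < 2L) return(0L)
    dd <- diff(peak_times_ms[idx])
    sum(abs(dd - s1_bcl) <= tol_ms)
  }, integer(1))
  rl <- run_lengths[run_lengths > 0L]
  n_s1 <- if (length(rl)) as.integer(names(sort(table(rl),
                                                decreasing = TRUE))[1]) + 1L
          else NA_integer_
  s2 <- vapply(trains, function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    last_d <- diff(peak_times_ms[idx[(length(idx) - 1L):length(idx)]])
    if (last_d <= s1_bcl + tol_ms) last_d else NA_real_
  }, numeric(1))
  gap <- if (length(boundary)) mean(d[boundary]) else NA_real_
  list(trains = trains, n_s1_per_train = n_s1, s2_intervals_ms = s2,
       inter_train_gap_ms = gap, centers = sort(km$centers))
}

# First principal component score series of a samples x channels matrix.
.pc1_series <- function(m) {
  m <- scale(m, center = TRUE, scale = FALSE)
  p <- prcomp(m, center = FALSE, scale. = FALSE, rank. = 1L)
  as.numeric(p$x[, 1L])
}

#' Validate candidate stimulus segments (conditions C1-C5)
#'
#' Candidate stimulation times are consolidated across channels and each is
#' tested against five conditions: C1 synchronous wavelet detection across
#' channels (within `sync_ms`); C2 energy-operator detection on the
#' high-passed trace coinciding with the wavelet segment; C3 the first
#' principal component across channels peaks inside the segment above 90%
#' of its global maximum; C4 the interval to a neighboring stimulus lies
#' within 10 samples of the S1 cycle length (or the candidate sits in the
#' S2 position: a short interval preceded by an S1 interval or followed by
#' an inter-train gap); C5 like C3 on the channel derivatives. A candidate
#' is trusted iff C1 and C2 hold in at least half the channels and C3-C5
#' hold.
#'
#' @param rec an [EgmRecording-class].
#' @param k accepted threshold factor from [estimateS1Bcl()].
#' @param s1_bcl S1 basic cycle length in ms.
#' @param sync_ms synchrony tolerance for C1/C2 (ms).
#' @param pc_frac amplitude fraction for C3/C5, applied against the median
#'   in-window peak of the quorum-passing candidates.
#' @param tol_ms C4 tolerance (ms; 10 samples at 1 kHz).
#' @return list with `trusted` / `discarded` annotation data frames (the
#'   window columns refer to the stimulating channel's segments) and
#'   per-candidate condition diagnostics.
#' @export
validateStimuli <- function(rec, k, s1_bcl, sync_ms = 5, pc_frac = 0.9,
                            tol_ms = 10, stim_channel = NULL) {
  fs <- samplingRate(rec)
  nc <- nChannels(rec)
  sync <- .ms2smp(sync_ms, fs)
  min_sep <- .ms2smp(50, fs)
  sig <- signalMatrix(rec)
  hp <- apply(sig, 2L, highpassStim, fs = fs)
  wseg <- lapply(seq_len(nc), function(ch) {
    d <- waveletSegments(hp[, ch], k, fs)
    .nms_segments(d$detection, d$segments, min_sep)
  })
  nseg <- lapply(seq_len(nc), function(ch) {
    d <- nleoSegments(hp[, ch], k, fs, lowpass_hz = NULL)
    .nms_segments(d$detection, d$segments, min_sep)
  })

  # consolidate candidate peaks across channels (one per stimulus);
  # groups are width-bounded so dense noise peaks cannot chain-merge
  allpk <- sort(unlist(lapply(wseg, `[[`, "peak")))
  if (length(allpk) == 0L)
    return(list(trusted = activityAnnotation(), discarded =
                activityAnnotation(), conditions = NULL))
  grp <- integer(length(allpk))
  g <- 1L; anchor <- allpk[1L]
  for (i in seq_along(allpk)) {
    if (allpk[i] - anchor > sync) { g <- g + 1L; anchor <- allpk[i] }
    grp[i] <- g
  }
  cand <- vapply(split(allpk, grp), function(p) round(median(p)), numeric(1))

  near_any <- function(segs, t0) any(abs(segs$peak - t0) <= sync)
  c12 <- vapply(cand, function(t0) {
    hits <- vapply(seq_len(nc), function(ch)
      near_any(wseg[[ch]], t0) && near_any(nseg[[ch]], t0), logical(1))
    sum(hits)
  }, numeric(1))
  quorum <- c12 >= nc / 2

  # per-candidate evaluation window: union of contributing wavelet segments
  win <- t(vapply(cand, function(t0) {
    s <- e <- integer(0)
    for (ch in seq_len(nc)) {
      segs <- wseg[[ch]]
      if (!nrow(segs)) next
      i <- which(abs(segs$peak - t0) <= sync)
      if (length(i)) { s <- c(s, segs$start[i]); e <- c(e, segs$end[i]) }
    }
    if (!length(s)) c(t0 - sync, t0 + sync + 1L) else c(min(s), max(e))
  }, numeric(2)))

  # C3 operates on the stimulation-isolated (high-passed) traces: the
  # condition tests the stimulus amplitude pattern across channels, and the
  # stimulation band is essentially free of physiological content, wander
  # and band-limited noise
  pc1 <- abs(.pc1_series(hp))
  pc1d <- abs(.pc1_series(apply(sig, 2L, function(x) c(0, diff(x)))))
  in_window_max <- function(series, w) {
    i1 <- max(1L, w[1] + 1L); i2 <- min(length(series), w[2])
    max(series[i1:i2])
  }
  # reference amplitude: the median in-window peak over quorum-passing
  # candidates (the plausible stimuli). Noise-free this equals the global
  # maximum; under noise it does not reject genuine stimuli whose peak sits
  # a few percent below the single luckiest beat, and a one-off artifact
  # spike cannot inflate it.
  pk3 <- vapply(seq_along(cand), function(i) in_window_max(pc1, win[i, ]),
                numeric(1))
  pk5 <- vapply(seq_along(cand), function(i) in_window_max(pc1d, win[i, ]),
                numeric(1))
  ref3 <- if (any(quorum)) median(pk3[quorum]) else max(pc1)
  ref5 <- if (any(quorum)) median(pk5[quorum]) else max(pc1d)
  c3 <- pk3 >= pc_frac * ref3
  c5 <- pk5 >= pc_frac * ref5

  ok_pre <- quorum & c3 & c5
  # C4 on the survivors' interval structure
  surv <- cand[ok_pre]
  c4s <- rep(FALSE, length(surv))
  if (length(surv) >= 2L) {
    tol <- .ms2smp(tol_ms, fs)
    bcl <- .ms2smp(s1_bcl, fs)
    dprev <- c(NA, diff(surv)); dnext <- c(diff(surv), NA)
    is_s1_like <- function(dd) !is.na(dd) & abs(dd - bcl) <= tol
    c4s <- is_s1_like(dprev) | is_s1_like(dnext) |
      # S2 position: short coupling interval, then an inter-train gap (or
      # end of recording)
      (!is.na(dprev) & dprev < bcl - tol &
         (is.na(dnext) | dnext > bcl + tol))
  } else if (length(surv) == 1L) {
    c4s <- TRUE  # a lone candidate has no interval evidence against it
  }
  c4 <- rep(FALSE, length(cand)); c4[ok_pre] <- c4s
  trusted_idx <- which(ok_pre & c4)

  # annotate with the stimulating-channel (max-amplitude) segment windows
  stim_ch <- if (is.null(stim_channel))
    which.max(apply(sig, 2L, function(x) max(x) - min(x)))
  else stim_channel
  seg_for <- function(t0) {
    s <- wseg[[stim_ch]]
    if (nrow(s)) {
      i <- which.min(abs(s$peak - t0))
      if (abs(s$peak[i] - t0) <= 2L * sync) return(s[i, ])
    }
    data.frame(start = t0 - sync, peak = t0, end = t0 + sync + 1L)
  }
  mk <- function(idx, label, trust) {
    if (!length(idx)) return(activityAnnotation())
    segs <- do.call(rbind, lapply(cand[idx], seg_for))
    activityAnnotation(channel = stim_ch, start = segs$start,
                       peak = segs$peak, end = segs$end, label = label,
                       train_index = NA_integer_, trusted = trust)
  }
  trusted <- mk(trusted_idx, "S1", TRUE)
  discarded <- mk(setdiff(seq_along(cand), trusted_idx), "discarded", FALSE)
  list(trusted = trusted, discarded = discarded,
       conditions = data.frame(time = cand, c12_channels = c12,
                               quorum = quorum, c3 = c3, c5 = c5, c4 = c4))
}

#' Tag trusted stimuli as S1 or S2
#'
#' Within each pacing train the last stimulus is tagged S2 when its
#' preceding interval is shorter than the S1 cycle length minus the
#' tolerance, or when the train holds one more stimulus than the S1 count
#' (positional tagging); trains without an identifiable S2 are flagged
#' incomplete.
#'
#' @param trusted trusted annotation table (stimulating-channel windows).
#' @param split result of [splitTrains()] on the trusted peak times.
#' @param s1_bcl S1 cycle length (ms).
#' @param fs sampling rate (Hz).
#' @param tol_ms tolerance (ms).
#' @return the annotation table with `label` set per stimulus,
#'   `train_index` filled, and an `incomplete` attribute (logical per
#'   train).
#' @export
tagS1S2 <- function(trusted, split, s1_bcl, fs = 1000, tol_ms = 10) {
  ann <- trusted[order(trusted$peak), ]
  times <- .smp2ms(ann$peak, fs)
  incomplete <- logical(length(split$trains))
  for (tr in seq_along(split$trains)) {
    idx <- split$trains[[tr]]
    ann$train_index[idx] <- tr
    ann$label[idx] <- "S1"
    if (length(idx) < 2L) { incomplete[tr] <- TRUE; next }
    last <- idx[length(idx)]
    dlast <- times[last] - times[last - 1L]
    positional <- !is.na(split$n_s1_per_train) &&
      length(idx) == split$n_s1_per_train + 1L
    if (dlast < s1_bcl - tol_ms || positional) {
      ann$label[last] <- "S2"
    } else {
      incomplete[tr] <- TRUE
    }
  }
  attr(ann, "incomplete") <- incomplete
  ann
}

#' Infer the full pacing protocol from a recording
#'
#' Runs stimulating-channel detection, iterative threshold / S1 BCL
#' estimation, stimulus validation (C1-C5), train splitting and S1/S2
#' tagging, without using any a-priori protocol knowledge.
#'
#' @param rec an [EgmRecording-class].
#' @param ... passed to [estimateS1Bcl()].
#' @return a `ProtocolEstimate` list: `k`, `s1_bcl_ms`, `n_trains`,
#'   `n_s1_per_train`, `s2_intervals_ms`, `inter_train_gap_ms`,
#'   `stim_channel`, `annotations` (trusted, labeled), `discarded`,
#'   `incomplete`, `converged`.
#' @export
segmentProtocol <- function(rec, ...) {
  fs <- samplingRate(rec)
  est <- estimateS1Bcl(rec, ...)
  val <- validateStimuli(rec, est$k, est$s1_bcl_ms,
                         stim_channel = est$stim_channel)
  .stop_if_not(nrow(val$trusted) > 0, "no trusted stimuli found")
  sp <- splitTrains(.smp2ms(sort(val$trusted$peak), fs), est$s1_bcl_ms)
  ann <- tagS1S2(val$trusted, sp, est$s1_bcl_ms, fs)
  structure(list(k = est$k, s1_bcl_ms = est$s1_bcl_ms,
                 n_trains = length(sp$trains),
                 n_s1_per_train = sp$n_s1_per_train,
                 s2_intervals_ms = sp$s2_intervals_ms,
                 inter_train_gap_ms = sp$inter_train_gap_ms,
                 stim_channel = est$stim_channel, annotations = ann,
                 discarded = val$discarded,
                 incomplete = attr(ann, "incomplete"),
                 converged = est$converged),
            class = "ProtocolEstimate")
}

#' @export
print.ProtocolEstimate <- function(x, ...) {
  cat(sprintf(paste0("ProtocolEstimate: S1 BCL %.1f ms (k = %.2f), ",
                     "%d trains x %s S1 + S2, gap %.0f ms, stim channel %d\n"),
              x$s1_bcl_ms, x$k, x$n_trains,
              ifelse(is.na(x$n_s1_per_train), "?", x$n_s1_per_train),
              x$inter_train_gap_ms, x$stim_channel))
  s2 <- x$s2_intervals_ms[!is.na(x$s2_intervals_ms)]
  cat("  S2 intervals (ms):", paste(round(s2), collapse = " "), "\n")
  invisible(x)
}
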